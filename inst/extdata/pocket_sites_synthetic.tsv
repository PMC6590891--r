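# SYNTHETIC substrate-pocket siteset for demonstrations and tests.
# The published pocket position list exists only as a supplementary figure
# image and could not be transcribed; this stand-in is generated, provisional,
# and NOT the published set. Positions refer to the synthetic template of
# simulateFamily() examples (root length 200).
template_id	site	pos	residue
SYN_TEMPLATE	pocket	25	G
SYN_TEMPLATE	pocket	60	L
SYN_TEMPLATE	pocket	104	F
SYN_TEMPLATE	pocket	141	S
SYN_TEMPLATE	pocket	180	Y
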