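name	annotated	label
T39G	TgTtCtGtTCaTtCaTcTc	AlexaFluor488
A40C	TgTtCtGtGAaTtCaTcTc	Digoxygenin
C42G	TgTtCtCtTAaTtCaTcTc	Biotin
TACco	TgTtCtGtTAaTtCaTcTc	none
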