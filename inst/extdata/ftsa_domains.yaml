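# FtsA subdomain residue ranges (author numbering; E. coli and
# V. maritimus positions coincide for the sites analysed here).
#
# The exact FtsA subdomain boundaries are not standardised; these are
# an approximate assignment derived from the actin-fold architecture of
# FtsA (subdomain 1A split between the N- and C-terminus; the 1C
# subdomain inserted where actin carries 1B, on the opposite side of
# the fold; 2A carrying the core with a C-terminal return segment; 2B
# inserted within 2A).  Edit per structure as needed -- every report
# states the boundary set used.
note: approximate actin-fold assignment for FtsA; edit per structure
IA: [[1, 81], [371, 396]]
IC: [[82, 160]]
IIA: [[161, 245], [321, 370]]
IIB: [[246, 320]]
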