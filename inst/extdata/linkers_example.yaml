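# Thiol-reactive cross-linker spans (Angstrom).  Only BMOE's ~8 A span
# is widely quoted; spans for other reagents depend on the source and
# must be confirmed by the user -- this file is an editable example,
# not a reference table.
BMOE: {span: 8.0, tolerance: 3.0}
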