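# Forbid FMA contraction so compiled arithmetic is bit-identical to the
# plain R reference engine (the training dynamics are chaotic: last-bit
# differences change pruning choices and whole learning curves).
PKG_CXXFLAGS = -ffp-contract=off
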