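# keep floating-point arithmetic strictly IEEE (no fused multiply-add), so
# the Euler integrator is bit-identical to its plain-R reference
PKG_CXXFLAGS = -ffp-contract=off
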