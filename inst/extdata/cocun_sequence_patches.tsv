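# Sequence positions of the CoCUN domain (local numbering 1-50) that carry no
# amide assignment in the packaged shift table but whose identity is attested
# elsewhere: P20 from the Phe-Pro motif (F865-P866 in full-length numbering,
# offset 846), V48 and L49 from the C-terminal LSxx(L/V)L motif. Positions 34,
# 36 and 50 remain unknown ('X') on purpose.
position	aa
20	P
48	V
49	L
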