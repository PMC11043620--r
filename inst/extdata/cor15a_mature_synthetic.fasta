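>cor15a_mature_SYNTHETIC stand-in | 89-residue mature chain surrogate; NOT the database sequence (offline build); composition chosen to reproduce the documented formal net charge of -6 (6 neutralizing Na+)
MAMSAEKAKDFVTSKAEEALQHAKDTAGSVKDATVEKAGEYKDTEDAGSETAKQHAEDA
VKSTAEGAKDATESAKNAVEKGTDFVKGLL
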