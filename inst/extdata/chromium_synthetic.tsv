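# Synthetic chromium optical constants: smooth representative NIR values
# (n ~ 3.0-3.4, k ~ 3.4-3.7), adequate for a 2 nm adhesion layer whose
# effect on the resonance position is sub-nanometre.
# columns: wavelength_nm n k
wavelength_nm	n	k
400	2.49	2.99
450	2.75	3.13
500	2.90	3.24
550	3.00	3.33
600	3.05	3.39
650	3.10	3.42
700	3.14	3.46
750	3.18	3.50
800	3.22	3.54
850	3.26	3.57
900	3.30	3.60
950	3.33	3.62
1000	3.36	3.64
1100	3.40	3.67
1200	3.42	3.68
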