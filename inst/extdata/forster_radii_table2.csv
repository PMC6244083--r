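# Forster radii R0 (Angstrom) for the Prodan (donor) / Nile Red (acceptor)
# FRET pair across solvent combinations. Rows: acceptor (NR) solvent.
# Columns: donor (P) solvent. Labels: t d a m w.
acceptor_solvent,t,d,a,m,w
t,29.7,40.7,43.6,46.4,37.2
d,29.1,40.0,43.3,47.9,39.7
a,29.1,40.1,43.5,48.3,40.1
m,26.7,37.1,40.6,46.5,39.5
w,24.5,33.4,36.0,40.8,35.0
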