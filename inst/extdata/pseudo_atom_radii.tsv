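# Side-chain pseudo-atom radii (Angstrom), one sphere per residue centred
# at the beta-carbon position, following the single-sphere side-chain
# representation of coarse-grained protein models (Levitt-style effective
# radii). Two columns: one-letter residue code, radius. Swappable via
# collision_model(pseudo_radii_file = ...). Glycine carries a small virtual
# site at the beta-carbon position.
G	1.00
A	1.90
S	1.90
C	2.10
T	2.15
P	2.15
V	2.30
D	2.25
N	2.30
I	2.45
L	2.45
E	2.40
Q	2.45
M	2.50
H	2.50
K	2.55
F	2.60
R	2.70
Y	2.65
W	2.80
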