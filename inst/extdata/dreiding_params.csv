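type,D0,R0,note
H_,0.0152,3.1950,generic hydrogen
H__HB,0.0100,3.1950,hydrogen on N/O/F (hydrogen-bond donor)
C_3,0.0951,3.8983,sp3 carbon
C_2,0.0951,3.8983,sp2 carbon
C_R,0.0951,3.8983,aromatic/resonant carbon
C_1,0.0951,3.8983,sp1 carbon
N_3,0.0774,3.6621,sp3 nitrogen
N_2,0.0774,3.6621,sp2 nitrogen
N_R,0.0774,3.6621,aromatic nitrogen
N_1,0.0774,3.6621,sp1 nitrogen
O_3,0.0957,3.4046,sp3 oxygen
O_2,0.0957,3.4046,sp2 oxygen
O_R,0.0957,3.4046,aromatic oxygen
F_,0.0725,3.4720,fluorine
P_3,0.3200,4.1500,phosphorus
S_3,0.3440,4.0300,sulfur
Cl,0.2833,3.9503,chlorine
Br,0.3700,4.3300,bromine
I_,0.5100,4.5100,iodine
B_3,0.0950,4.0200,boron
Si3,0.3100,4.2700,silicon
Na,0.5000,3.1440,sodium cation
K_,0.5000,3.4720,potassium cation
Mg,0.3250,3.0210,magnesium
Ca,0.0500,3.4720,calcium
X_,0.1500,3.4000,reserved toy element
Y_,0.1500,3.4000,reserved toy element
Z_,0.1500,3.4000,reserved toy element
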