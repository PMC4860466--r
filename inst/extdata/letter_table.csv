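letter,c1,c2,c3,c4,c5,c6,c7,c8,c9
a,0.03,0.07,0.04,0.21,0.14,0.24,0.01,0.02,0.01
b,0.23,0.23,0.08,0.26,0.12,0.22,0.01,0.18,0.01
c,0.04,0.08,0.02,0.23,0.10,0.11,0.01,0.03,0.01
d,0.01,0.17,0.00,0.23,0.13,0.22,0.23,0.23,0.08
e,0.03,0.08,0.03,0.24,0.16,0.20,0.01,0.03,0.01
f,0.10,0.20,0.02,0.08,0.24,0.08,0.01,0.10,0.00
g,0.01,0.02,0.01,0.22,0.14,0.23,0.12,0.20,0.10
h,0.23,0.04,0.01,0.25,0.15,0.21,0.02,0.12,0.02
i,0.00,0.09,0.00,0.00,0.22,0.00,0.00,0.05,0.00
j,0.00,0.09,0.00,0.00,0.22,0.00,0.06,0.14,0.00
k,0.23,0.03,0.01,0.25,0.18,0.14,0.02,0.10,0.06
l,0.00,0.23,0.00,0.00,0.24,0.00,0.00,0.06,0.00
m,0.02,0.03,0.02,0.24,0.22,0.24,0.02,0.02,0.02
n,0.02,0.03,0.01,0.24,0.14,0.23,0.01,0.02,0.01
o,0.03,0.07,0.03,0.22,0.11,0.22,0.01,0.03,0.01
p,0.02,0.03,0.01,0.25,0.13,0.22,0.19,0.07,0.01
q,0.01,0.03,0.02,0.22,0.13,0.25,0.01,0.07,0.19
r,0.02,0.02,0.00,0.22,0.12,0.06,0.02,0.01,0.00
s,0.03,0.09,0.03,0.14,0.15,0.13,0.02,0.04,0.01
t,0.04,0.18,0.02,0.06,0.22,0.06,0.00,0.08,0.02
u,0.02,0.02,0.02,0.23,0.12,0.24,0.01,0.05,0.02
v,0.02,0.01,0.02,0.20,0.08,0.20,0.01,0.09,0.01
w,0.03,0.02,0.03,0.22,0.18,0.22,0.02,0.10,0.02
x,0.02,0.01,0.02,0.15,0.14,0.15,0.02,0.01,0.02
y,0.02,0.01,0.02,0.19,0.09,0.19,0.05,0.11,0.01
z,0.03,0.10,0.03,0.10,0.15,0.09,0.03,0.11,0.03
è,0.08,0.12,0.03,0.24,0.16,0.20,0.01,0.03,0.01
é,0.03,0.12,0.08,0.24,0.16,0.20,0.01,0.03,0.01
î,0.05,0.12,0.05,0.00,0.22,0.00,0.00,0.05,0.00
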