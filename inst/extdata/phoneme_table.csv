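symbol,cv,place,manner
p,0.5,0.05,0.10
b,0.5,0.05,0.12
t,0.5,0.35,0.10
d,0.5,0.35,0.12
k,0.5,0.75,0.10
g,0.5,0.75,0.12
m,0.5,0.05,0.25
n,0.5,0.35,0.25
ŋ,0.5,0.75,0.25
ɲ,0.5,0.60,0.25
f,0.5,0.15,0.55
v,0.5,0.15,0.57
s,0.5,0.35,0.55
z,0.5,0.35,0.57
ʃ,0.5,0.45,0.55
ʒ,0.5,0.45,0.57
x,0.5,0.75,0.55
ɣ,0.5,0.75,0.57
ʁ,0.5,0.85,0.57
r,0.5,0.35,0.40
l,0.5,0.35,0.90
j,0.5,0.60,0.75
w,0.5,0.05,0.75
ɥ,0.5,0.60,0.77
h,0.5,0.95,0.55
i,1.0,0.10,0.10
y,1.0,0.15,0.10
ɪ,1.0,0.15,0.20
ʏ,1.0,0.20,0.20
e,1.0,0.10,0.30
ø,1.0,0.15,0.30
ɛ,1.0,0.10,0.65
œ,1.0,0.15,0.65
a,1.0,0.25,0.90
ɑ,1.0,0.80,0.90
ɔ,1.0,0.85,0.65
o,1.0,0.90,0.30
u,1.0,0.90,0.10
ə,1.0,0.50,0.50
ẽ,1.0,0.12,0.35
ã,1.0,0.30,0.92
õ,1.0,0.88,0.35
ĩ,1.0,0.12,0.15
ũ,1.0,0.88,0.15
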