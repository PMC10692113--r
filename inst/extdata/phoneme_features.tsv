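phoneme	voiced consonant	unvoiced consonant	plosive	fricative	nasal	strident	labial	coronal	dorsal	anterior	front	back	high	low
p	0	1	1	0	0	0	1	0	0	1	0	0	0	0
b	1	0	1	0	0	0	1	0	0	1	0	0	0	0
t	0	1	1	0	0	0	0	1	0	1	0	0	0	0
d	1	0	1	0	0	0	0	1	0	1	0	0	0	0
k	0	1	1	0	0	0	0	0	1	0	0	0	0	0
g	1	0	1	0	0	0	0	0	1	0	0	0	0	0
ch	0	1	1	1	0	1	0	1	0	0	0	0	0	0
jh	1	0	1	1	0	1	0	1	0	0	0	0	0	0
f	0	1	0	1	0	1	1	0	0	1	0	0	0	0
v	1	0	0	1	0	1	1	0	0	1	0	0	0	0
th	0	1	0	1	0	0	0	1	0	1	0	0	0	0
dh	1	0	0	1	0	0	0	1	0	1	0	0	0	0
s	0	1	0	1	0	1	0	1	0	1	0	0	0	0
z	1	0	0	1	0	1	0	1	0	1	0	0	0	0
sh	0	1	0	1	0	1	0	1	0	0	0	0	0	0
zh	1	0	0	1	0	1	0	1	0	0	0	0	0	0
hh	0	1	0	1	0	0	0	0	0	0	0	0	0	0
m	1	0	0	0	1	0	1	0	0	1	0	0	0	0
n	1	0	0	0	1	0	0	1	0	1	0	0	0	0
ng	1	0	0	0	1	0	0	0	1	0	0	0	0	0
l	1	0	0	0	0	0	0	1	0	1	0	0	0	0
r	1	0	0	0	0	0	0	1	0	0	0	0	0	0
w	1	0	0	0	0	0	1	0	1	0	0	1	1	0
y	1	0	0	0	0	0	0	0	1	0	1	0	1	0
iy	0	0	0	0	0	0	0	0	0	0	1	0	1	0
ih	0	0	0	0	0	0	0	0	0	0	1	0	1	0
eh	0	0	0	0	0	0	0	0	0	0	1	0	0	0
ae	0	0	0	0	0	0	0	0	0	0	1	0	0	1
ah	0	0	0	0	0	0	0	0	0	0	0	1	0	1
aa	0	0	0	0	0	0	0	0	0	0	0	1	0	1
ao	0	0	0	0	0	0	0	0	0	0	0	1	0	0
oh	0	0	0	0	0	0	0	0	0	0	0	1	0	1
uh	0	0	0	0	0	0	0	0	0	0	0	1	1	0
uw	0	0	0	0	0	0	0	0	0	0	0	1	1	0
er	0	0	0	0	0	0	0	0	0	0	0	1	0	0
ax	0	0	0	0	0	0	0	0	0	0	0	1	0	0
ey	0	0	0	0	0	0	0	0	0	0	1	0	0	0
ay	0	0	0	0	0	0	0	0	0	0	1	0	0	1
oy	0	0	0	0	0	0	0	0	0	0	0	1	0	0
aw	0	0	0	0	0	0	0	0	0	0	0	1	0	1
ow	0	0	0	0	0	0	0	0	0	0	0	1	0	0
ia	0	0	0	0	0	0	0	0	0	0	1	0	1	0
ea	0	0	0	0	0	0	0	0	0	0	1	0	0	0
ua	0	0	0	0	0	0	0	0	0	0	0	1	1	0
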