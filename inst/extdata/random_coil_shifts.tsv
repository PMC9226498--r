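aa	atom	shift_ppm
A	CA	52.5
A	CB	19.1
A	C	177.8
A	N	123.8
A	H	8.24
A	HA	4.32
R	CA	56.0
R	CB	30.9
R	C	176.3
R	N	120.5
R	H	8.23
R	HA	4.34
N	CA	53.1
N	CB	38.9
N	C	175.2
N	N	118.7
N	H	8.40
N	HA	4.74
D	CA	54.2
D	CB	41.1
D	C	176.3
D	N	120.4
D	H	8.34
D	HA	4.64
C	CA	58.2
C	CB	28.0
C	C	174.6
C	N	118.8
C	H	8.32
C	HA	4.55
Q	CA	55.7
Q	CB	29.4
Q	C	176.0
Q	N	119.8
Q	H	8.32
Q	HA	4.34
E	CA	56.6
E	CB	29.9
E	C	176.6
E	N	120.2
E	H	8.42
E	HA	4.35
G	CA	45.1
G	C	174.9
G	N	108.8
G	H	8.33
G	HA	3.96
H	CA	55.0
H	CB	29.0
H	C	174.1
H	N	118.2
H	H	8.42
H	HA	4.73
I	CA	61.1
I	CB	38.8
I	C	176.4
I	N	119.9
I	H	8.00
I	HA	4.17
L	CA	55.1
L	CB	42.4
L	C	177.6
L	N	121.8
L	H	8.16
L	HA	4.34
K	CA	56.2
K	CB	33.1
K	C	176.6
K	N	120.4
K	H	8.29
K	HA	4.32
M	CA	55.4
M	CB	32.9
M	C	176.3
M	N	119.6
M	H	8.28
M	HA	4.48
F	CA	57.7
F	CB	39.6
F	C	175.8
F	N	120.3
F	H	8.30
F	HA	4.62
P	CA	63.3
P	CB	32.1
P	C	177.3
P	HA	4.42
S	CA	58.3
S	CB	63.8
S	C	174.6
S	N	115.7
S	H	8.31
S	HA	4.47
T	CA	61.8
T	CB	69.8
T	C	174.7
T	N	113.6
T	H	8.15
T	HA	4.35
W	CA	57.5
W	CB	29.6
W	C	176.1
W	N	121.3
W	H	8.25
W	HA	4.66
Y	CA	57.9
Y	CB	38.8
Y	C	175.9
Y	N	120.3
Y	H	8.28
Y	HA	4.55
V	CA	62.2
V	CB	32.9
V	C	176.3
V	N	119.2
V	H	8.19
V	HA	4.12
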