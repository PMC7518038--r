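H
  PoseSAR fragment

  1  0  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
M  END
> <LABEL>
H

> <LINK_ATOM>
1

$$$$
Me
  PoseSAR fragment

  4  3  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.3633    1.0277    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.3633   -0.5138    0.8900 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.3633   -0.5138   -0.8900 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  3  1  0  0  0  0
  1  4  1  0  0  0  0
M  END
> <LABEL>
Me

> <LINK_ATOM>
1

$$$$
OMe
  PoseSAR fragment

  5  4  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5125    1.3350    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6427    1.6742   -1.0277 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.1882    1.9931    0.5138 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4735    1.3553    0.5138 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
  2  4  1  0  0  0  0
  2  5  1  0  0  0  0
M  END
> <LABEL>
OMe

> <LINK_ATOM>
1

$$$$
Cl
  PoseSAR fragment

  1  0  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 Cl  0  0  0  0  0  0  0  0  0  0  0  0
M  END
> <LABEL>
Cl

> <LINK_ATOM>
1

$$$$
Br
  PoseSAR fragment

  1  0  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 Br  0  0  0  0  0  0  0  0  0  0  0  0
M  END
> <LABEL>
Br

> <LINK_ATOM>
1

$$$$
F
  PoseSAR fragment

  1  0  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 F   0  0  0  0  0  0  0  0  0  0  0  0
M  END
> <LABEL>
F

> <LINK_ATOM>
1

$$$$
tBu
  PoseSAR fragment

 13 12  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5100    1.4425    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5100   -0.7213    1.2492 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5100   -0.7213   -1.2492 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6311    1.7850   -1.0277 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.2080    2.0817    0.5138 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4702    1.4884    0.5138 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6000   -0.7213    1.2492 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1466   -0.2074    2.1392 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1466   -1.7489    1.2492 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6000   -0.7213   -1.2492 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1466   -1.7489   -1.2492 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1466   -0.2074   -2.1392 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  3  1  0  0  0  0
  1  4  1  0  0  0  0
  2  5  1  0  0  0  0
  2  6  1  0  0  0  0
  2  7  1  0  0  0  0
  3  8  1  0  0  0  0
  3  9  1  0  0  0  0
  3 10  1  0  0  0  0
  4 11  1  0  0  0  0
  4 12  1  0  0  0  0
  4 13  1  0  0  0  0
M  END
> <LABEL>
tBu

> <LINK_ATOM>
1

$$$$
CCH
  PoseSAR fragment

  3  2  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2000   -0.0000   -0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.2600   -0.0000   -0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  3  0  0  0  0
  2  3  1  0  0  0  0
M  END
> <LABEL>
CCH

> <LINK_ATOM>
1

$$$$
CN
  PoseSAR fragment

  2  1  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.1600   -0.0000   -0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  3  0  0  0  0
M  END
> <LABEL>
CN

> <LINK_ATOM>
1

$$$$
COOEt
  PoseSAR fragment

 10  9  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6335    1.0543    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.4802   -1.2510    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5270   -2.2940    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.1393   -3.6602   -0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1486   -2.1956   -0.8900 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1486   -2.1956    0.8900 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.2985   -3.9867   -1.0277 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5014   -4.3769    0.5138 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.0985   -3.5966    0.5138 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0  0  0  0
  1  3  1  0  0  0  0
  3  4  1  0  0  0  0
  4  5  1  0  0  0  0
  4  6  1  0  0  0  0
  4  7  1  0  0  0  0
  5  8  1  0  0  0  0
  5  9  1  0  0  0  0
  5 10  1  0  0  0  0
M  END
> <LABEL>
COOEt

> <LINK_ATOM>
1

$$$$
NH2
  PoseSAR fragment

  3  2  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2953    0.9659    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2953   -0.9659    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  3  1  0  0  0  0
M  END
> <LABEL>
NH2

> <LINK_ATOM>
1

$$$$
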