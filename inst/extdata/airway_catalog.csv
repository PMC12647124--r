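segment_label,lobe,generation,parent
LL-A,LL,1,
LL-B,LL,2,LL-A
LL-Ba,LL,3,LL-B
LL-C,LL,3,LL-B
LL-BaI,LL,4,LL-Ba
LL-Ca,LL,4,LL-C
LL-D,LL,4,LL-C
LL-BaII,LL,5,LL-BaI
LL-CaI,LL,5,LL-Ca
LL-Da,LL,5,LL-D
LL-E,LL,5,LL-D
LL-CaII,LL,6,LL-CaI
LL-DaI,LL,6,LL-Da
LL-Ea,LL,6,LL-E
LL-F,LL,6,LL-E
LL-DaII,LL,7,LL-DaI
LL-EaI,LL,7,LL-Ea
LL-Fa,LL,7,LL-F
LL-G,LL,7,LL-F
LL-EaII,LL,8,LL-EaI
LL-FaI,LL,8,LL-Fa
LL-Ga,LL,8,LL-G
LL-H,LL,8,LL-G
LL-FaII,LL,9,LL-FaI
LL-GaI,LL,9,LL-Ga
LL-Ha,LL,9,LL-H
LL-I,LL,9,LL-H
LL-GaII,LL,10,LL-GaI
LL-HaI,LL,10,LL-Ha
LL-Ia,LL,10,LL-I
LL-J,LL,10,LL-I
LL-HaII,LL,11,LL-HaI
LL-IaI,LL,11,LL-Ia
LL-K,LL,11,LL-J
RCL-A,RCL,1,
RCL-B,RCL,2,RCL-A
RCL-Ba,RCL,3,RCL-B
RCL-C,RCL,3,RCL-B
RCL-BaI,RCL,4,RCL-Ba
RCL-Ca,RCL,4,RCL-C
RCL-D,RCL,4,RCL-C
RCL-BaII,RCL,5,RCL-BaI
RCL-CaI,RCL,5,RCL-Ca
RCL-Da,RCL,5,RCL-D
RCL-E,RCL,5,RCL-D
RCL-CaII,RCL,6,RCL-CaI
RCL-DaI,RCL,6,RCL-Da
RCL-Ea,RCL,6,RCL-E
RCL-F,RCL,6,RCL-E
RCL-DaII,RCL,7,RCL-DaI
RCL-EaI,RCL,7,RCL-Ea
RCL-Fa,RCL,7,RCL-F
RCL-G,RCL,7,RCL-F
RCL-EaII,RCL,8,RCL-EaI
RCL-FaI,RCL,8,RCL-Fa
RCL-Ga,RCL,8,RCL-G
RCL-H,RCL,8,RCL-G
RCL-FaII,RCL,9,RCL-FaI
RCL-GaI,RCL,9,RCL-Ga
RCL-Ha,RCL,9,RCL-H
RCL-I,RCL,9,RCL-H
RCL-GaII,RCL,10,RCL-GaI
RCL-HaI,RCL,10,RCL-Ha
RCL-Ia,RCL,10,RCL-I
RCL-J,RCL,10,RCL-I
RCL-HaII,RCL,11,RCL-HaI
RCL-IaI,RCL,11,RCL-Ia
RCL-K,RCL,11,RCL-J
RLL-A,RLL,1,
RLL-B,RLL,2,RLL-A
RLL-Ba,RLL,3,RLL-B
RLL-C,RLL,3,RLL-B
RLL-BaI,RLL,4,RLL-Ba
RLL-Ca,RLL,4,RLL-C
RLL-D,RLL,4,RLL-C
RLL-BaII,RLL,5,RLL-BaI
RLL-CaI,RLL,5,RLL-Ca
RLL-Da,RLL,5,RLL-D
RLL-E,RLL,5,RLL-D
RLL-CaII,RLL,6,RLL-CaI
RLL-DaI,RLL,6,RLL-Da
RLL-Ea,RLL,6,RLL-E
RLL-F,RLL,6,RLL-E
RLL-DaII,RLL,7,RLL-DaI
RLL-EaI,RLL,7,RLL-Ea
RLL-Fa,RLL,7,RLL-F
RLL-G,RLL,7,RLL-F
RLL-EaII,RLL,8,RLL-EaI
RLL-FaI,RLL,8,RLL-Fa
RLL-Ga,RLL,8,RLL-G
RLL-H,RLL,8,RLL-G
RLL-FaII,RLL,9,RLL-FaI
RLL-GaI,RLL,9,RLL-Ga
RLL-Ha,RLL,9,RLL-H
RLL-I,RLL,9,RLL-H
RLL-GaII,RLL,10,RLL-GaI
RLL-HaI,RLL,10,RLL-Ha
RLL-Ia,RLL,10,RLL-I
RLL-J,RLL,10,RLL-I
RLL-HaII,RLL,11,RLL-HaI
RLL-IaI,RLL,11,RLL-Ia
RLL-K,RLL,11,RLL-J
RML-A,RML,1,
RML-B,RML,2,RML-A
RML-Ba,RML,3,RML-B
RML-C,RML,3,RML-B
RML-BaI,RML,4,RML-Ba
RML-Ca,RML,4,RML-C
RML-D,RML,4,RML-C
RML-BaII,RML,5,RML-BaI
RML-CaI,RML,5,RML-Ca
RML-Da,RML,5,RML-D
RML-E,RML,5,RML-D
RML-CaII,RML,6,RML-CaI
RML-DaI,RML,6,RML-Da
RML-Ea,RML,6,RML-E
RML-F,RML,6,RML-E
RML-DaII,RML,7,RML-DaI
RML-EaI,RML,7,RML-Ea
RML-Fa,RML,7,RML-F
RML-G,RML,7,RML-F
RML-EaII,RML,8,RML-EaI
RML-FaI,RML,8,RML-Fa
RML-Ga,RML,8,RML-G
RML-H,RML,8,RML-G
RML-FaII,RML,9,RML-FaI
RML-GaI,RML,9,RML-Ga
RML-Ha,RML,9,RML-H
RML-I,RML,9,RML-H
RML-GaII,RML,10,RML-GaI
RML-HaI,RML,10,RML-Ha
RML-Ia,RML,10,RML-I
RML-J,RML,10,RML-I
RML-HaII,RML,11,RML-HaI
RML-IaI,RML,11,RML-Ia
RML-K,RML,11,RML-J
RUL-A,RUL,1,
RUL-B,RUL,2,RUL-A
RUL-Ba,RUL,3,RUL-B
RUL-C,RUL,3,RUL-B
RUL-BaI,RUL,4,RUL-Ba
RUL-Ca,RUL,4,RUL-C
RUL-D,RUL,4,RUL-C
RUL-BaII,RUL,5,RUL-BaI
RUL-CaI,RUL,5,RUL-Ca
RUL-Da,RUL,5,RUL-D
RUL-E,RUL,5,RUL-D
RUL-CaII,RUL,6,RUL-CaI
RUL-DaI,RUL,6,RUL-Da
RUL-Ea,RUL,6,RUL-E
RUL-F,RUL,6,RUL-E
RUL-DaII,RUL,7,RUL-DaI
RUL-EaI,RUL,7,RUL-Ea
RUL-Fa,RUL,7,RUL-F
RUL-G,RUL,7,RUL-F
RUL-EaII,RUL,8,RUL-EaI
RUL-FaI,RUL,8,RUL-Fa
RUL-Ga,RUL,8,RUL-G
RUL-H,RUL,8,RUL-G
RUL-FaII,RUL,9,RUL-FaI
RUL-GaI,RUL,9,RUL-Ga
RUL-Ha,RUL,9,RUL-H
RUL-I,RUL,9,RUL-H
RUL-GaII,RUL,10,RUL-GaI
RUL-HaI,RUL,10,RUL-Ha
RUL-Ia,RUL,10,RUL-I
RUL-J,RUL,10,RUL-I
RUL-HaII,RUL,11,RUL-HaI
RUL-IaI,RUL,11,RUL-Ia
RUL-K,RUL,11,RUL-J
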