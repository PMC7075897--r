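A0A0B4JDA0
A0A0B4K765
A0A0B4K7J2
A0A0B4K851
A0A0B4KEI5
A0A0B4KHB1
A0A0B4LGZ6
A1Z8U0
A9UND8
B7Z002
D0Z769
E1JGX3
E1JHV6
E1JI46
M9PFM5
N0D8I3
O46036
P08928
P19109
P48591
P51140
P91638
Q24478
Q7K0D8
Q7KJV9
Q7KK96
Q7KN75
Q86NP2
Q8INM3
Q8IQV9
Q8MZI3
Q8T0L3
Q8T9D1
Q94517
Q9GYU8
Q9V3P3
Q9V3Y5
Q9V4C8
Q9V4P1
Q9VF03
Q9VGL0
Q9VGW6
Q9VHP0
Q9VP57
Q9VUV9
Q9VYF3
Q9W1X4
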