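a1:
- 16
- 35
a2:
- 54
- 70
a3:
- 73
- 84
a4:
- 89
- 100
a5:
- 107
- 126
a6:
- 130
- 146
a7:
- 150
- 158
a8:
- 160
- 165
a9:
- 169
- 186
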