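total_sterols:
- X30
- X31
- X32
- X36
- X37
- X39
total_steryl_esters:
- X33
- X34
- X35
- X40
pm_ergosterol:
- X36
- X37
- X39
total_ergosterol:
- X32
- X36
- X37
- X39
total_erg_esters:
- X35
- X40
IPC:
- X8
- X20
MIPC:
- X18
- X21
MIP2C:
- X19
- X22
CS:
- X8
- X18
- X19
- X20
- X21
- X22
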