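name	priority	retro	forward
amide_coupling	10	[C:1](=[O:2])[N:3]>>[C:1](=[O:2])O.[N:3]	[C:1](=[O:2])[OH].[NH:3]>>[C:1](=[O:2])[N:3]
sulfonamide	20	[S:1](=[O:2])(=[O:3])[N:4]>>[S:1](=[O:2])(=[O:3])Cl.[N:4]	[S:1](=[O:2])(=[O:3])Cl.[NH:4]>>[S:1](=[O:2])(=[O:3])[N:4]
ester	30	[C:1](=[O:2])[O:3][CX4:4]>>[C:1](=[O:2])O.[O:3][CX4:4]	[C:1](=[O:2])[OH].[OH:3][CX4:4]>>[C:1](=[O:2])[O:3][CX4:4]
urea	40	[N:1][C:2](=[O:3])[N:4]>>[N:1]=[C:2]=[O:3].[N:4]	[N:1]=[C:2]=[O:3].[NH:4]>>[N:1][C:2](=[O:3])[N:4]
n_alkylation	50	[CX4:1][NX3:2]>>[CX4:1]Br.[N:2]	[CX4:1][Cl,Br,I].[NH:2]>>[CX4:1][N:2]
williamson_ether	60	[CX4:1][OX2:2][CX4:3]>>[CX4:1]Br.[O:2][CX4:3]	[CX4:1][Cl,Br,I].[OH:2][CX4:3]>>[CX4:1][O:2][CX4:3]
suzuki_biaryl	70	[c:1]-!@[c:2]>>[c:1]Br.[c:2]B(O)O	[c:1][Cl,Br,I].[c:2]B([OH])[OH]>>[c:1]-[c:2]
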