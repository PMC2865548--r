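>PENK_human_synthetic synthetic stand-in proenkephalin (7 opioid cores)
MDHVTMAVCPQDMVSCVWTWDQTDQCHCASEPWACTCNGTGCSQGGLLCPTQTGLCGPHC
GECPDPPAIQAKRYGGFMEPAIGPMVCSHDKRQAETHCKRYGGFMIEPASEWPPVEVKRT
SGVWCKRYGGFMGWANPGCISDSDKRETADPCKRYGGFMVWIGMSACMCSVKRCLESPNK
RYGGFLGLWWVSWSPHMDKRNQEQDAKRYGGFMSWDSSHWIADEVKRHQHTHDKRYGGFM
ALNHGCWCMPIHKRDDVQAE
>PDYN_human_synthetic synthetic stand-in prodynorphin (3 opioid cores + 2 relics)
MPADPANLNCQHHSLAEWNNPTLCVTHCGQTGENCEHVAWHCPNQNSTCAVIAWTCQPQL
MPCTAPTDESGKRVGGLLATAEHCWHPMKRYAGFLPPAVMGQTTVKRYGGFLLQSSEHWQ
ISCDPCKRHGLNQKRYGGFLQLEHWTQCASSWGDKRPEDNLKRYGGFLLLASDMWLCGVM
TEKRTDMGM
>PNOC_human_synthetic synthetic stand-in prepronociceptin (1 opioid core FGGFI)
MAGSCESWNAEECCCDTAVTVSILWAHCEDMEHQCMGMQWMCIPDTDTCEVIAVWCQADM
GCCEVNCSTCNSSHCDQANGLPHVGWMGMHVETGQWTINKRFGGFIGTEAGEHVNMEMNK
RQHQLTDEMWLHCNCLCMMLI
>POMC_human_synthetic synthetic stand-in proopiomelanocortin (1 core + 3 HFRW)
MTWNPGLWICQITNWSPATTNDGAHDNCSWAPWWCMGAGVWCTDAAETCLIQGELCTHTP
ACCEEVNQWAMKRDVSPHFRWQQHNCLKRPSCSMDMVQIKREEQAHFRWVNDAIVNGNNS
TTTKRKREWPMTNPQLDHFRWINLHEWKRKRYGGFMMVHMSLNVNWTDLQVQAVEAAN
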