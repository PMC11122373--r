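>21
AVIKNKALQMCWNRTCVWAANEQLQASLDLIVFYMSGLRNTCLMLMLRLMFVSELLVLDRELHKDMVAV
>33
APKREVAFMELLTRCLVTVLNNQAQTKLQLIDCYLADLLMRVLNRLAMMMLMAHLNLLMQLAYQGMHAQ
>45
ADIMMCALGWEISVVKVFGYNNPSMDQLLNNKWFLGNGWNYKFMRMEVMLGMRAWSLTTVENLLIELIG
>51
LVSCQFNSMWKFTSMEVWNYNTMLASQMWGHVYTNATLLANLLMGMMIMCKKLRLTSWMATDVVLGGDW
>59
GHRCNMARANLLTSMASIGLYTMYDGIMYTECILIHDNQIRVKMWLAQMFKMEVSAFDLRDDSSLYHLG
>60
QANGMTTLMFLNILNWVWHYQTMPRAAEDGYVHWLNIGVKMELMRMCWCMWKARACAHMLQDDTQFSSH
>63
SIVGQGAQQMLVSKIKCTVANEWLDRSMLTSKFAMFVLLNEIDMLDIMLEAMGISLLEDREHQTRRVNY
>64
PDKCAMASEWLLGTNWCWMYYGRQASIYQTIHFYLAMKAGYQFVYMFVMMAMRHWLIAMMRKDYRMLAK
>70
AVINQVAWDQWNTLMTPDVYACCLIALRLGIFTALACGTARLDMRYTIRQEDKQLVMQMNLLDKIVFEV
>71
AVIRDVAKWWLLHNMWSIVQTNQQIGNTHDQVCNSYDTLVRVLMSPEMIFDATRLDNFEVLHCYLMMQV
>75
CNSLILKWLLFGGDHWHLRGVTQILTREIACTAWMEQWLSVDSSLMSNNRASNYMNVERCWLWKETDAA
>76
SIQGQGARQCLVSKLKCTVANEWLDRWMLTSKFAMFVLLNEIDMLDIMLEAMGISIEEDREHQTRRVNY
>77
GTIDQRWWNHFDSTTERTVHEMTSDCHMRMQKSMTQNRCSMVVVPHRMRYVGYKGMRNINNMGYCGDAA
>78
LELLRAEETAHTSTLHIDVEVISTTAFAYCRMDQFTQISNDALETMNQLESGLAWMAVRGCYMMTCVGE
>79
VTMQFSFNSLLEGRAEAHMGTILITAMAITIKKLKGRGAFGKKLLEWNMAMACSHNAQLGGMDFQHKEG
>83
SEGAAKASELLQSMNLCWMYIGCQNSIQQTIAVYLAMQAGMQFVYMFVCSAAQHWLKTMDRKNYLMLVK
>84
ADDQNTEIVWLLVSQWWWLYNFVEIANLLLVSNMNTIWNNRMKGRMNMNCLMYRMLGNRGMLCLQDGQA
>86
TAVLIVFLEGLSAATGRHVGARMPDAAYSKNYHMMFAAAQACDYRGNMKSLARGFAAAQWMMTWVSFIS
>91
NACEFKALDVDRGNLHDAHRNCGGRKNNAMQVEAMIVLSNGFGAGPNVWMLKAALLEVMTLLTCDTLKR
>92
GVIRGHARVRALAGRMYALLDVTWCADSKSRRIMQGGFLVHIFNQEWTLYGELAKTTWVWRHFFQIMDF
>93
CKQMQALHAFSSEADRQHLQACAWKGMNVGCVLEVVVLDAIMGNQNNDQYFSTNIMMQMSTVFWNLQGM
>94
PCVWTGFREFKGGQRGKERLAMCEDLMCEADWWGGNQNRDRGSIFTRVKGSGALGKISIAERGARNNAV
>98
TMNTIMMKVSFCAGARIVHLAVLVIGLDVDRSELMDTAIDTMVHWNFAISEVYMVLWGSSQSKSDCQEV
>100
ACTETIWTVTCNGHLEMRTYWAYCAMFTFMESHITDNLHWTAAMFTQEVRTRTFYAGVQGNSMWWTVRN
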