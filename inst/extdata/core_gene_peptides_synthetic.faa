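>ppolb synthetic seed profile (randomly generated, fixed)
QGNQRSKSGRYNACPRSCLRRGGLCERLKYQFQQGTFEYFNKYSYSIVSIMDMLSHTSARNYGTYNAYDL
GYLSYTVKRDLIDKNSMKCHRQEEEVLALVVDIAMRFFMETGLCAKQIDVYPDRGGVARGASFPCWFMNE
NKLLWQHTGIHLFTLQFLMYLIFPVHGKKVQIRNAEDTGVGASREAPITLTILSQIIIRSGMLYDVDQIE
MIETTSAKQDIKRRGEFEETIKIFGASGAKNILVMFTNYFEHNASDLHKSTYPASGLQEPWMSTSGGGRK
KFKGQFTRDRRCTHSVKPDDTVEAVAEQSELVYMDGCSRLIADGPYRQDAPINPDTFAVPTHAARLRESA
AQLTNPPLRMCQELITLAYVLADEYRLGNIRAELATNRGRDGENCTGNQFPGKYRIVTLGSVQKQFLEPF
APISFMRIGNRLKEREEPRDERVVIASSCLYVYGAVSLVIEASKKPKGWANYRGPVPPSRLIYVAYTKNV
PAGPPYTTEASFGENVVLANKAQSGPARVLSHTVFMPNNVIAVGASEGDYEEVTDKEQVIEADKDKQDKY
ADYDEMGVVDMPGEKQIRKFANQAEIDVIIRISHRSRSNKTPEETNNGCNGTDQIAAKSLLYLPVNRSNL
DQIATYKGKHDPNGLTRVERIQARFELHQDGLQNPGDVYLHFLPGLTWISSDGAPSTAVAASRKVGDTVS
SLGCYDAREGQVVISKAADMGLARVNKWEKYARSSYFSCVRPHAEVHTEPKYGQIDALRREPIGSGAEPS
KPVQRLVGLQLLGDMFYGGIPIGVTGLMVLTFEGVLAEGLTRERKTTMTCKIQQIGIGLGEGFEADMPGK
ETRIAHADQV
>atp synthetic seed profile (randomly generated, fixed)
AETTMLGMVWFFDPVTSELMLIQGRNQGQEVFSSTSVESFPSSPSKNERGVDIKSTGPSLSMNEYLLDTM
LLRSVTQKGYWSRLDRPGQREWKDATDVTTVPENQVITFSGLKLLSDVLGLCKDLDKYINSGVANYEALC
ASPGSAAAVRGHIAQINLSCYILSWLDCGLIQATVCKTLKAAQKGLFDNFRLSVPSLEDEPLNLICSAVY
MSVPIKYPQSFKKAEKEVFKFQADPKTMQVAAFAVDFIYPFSENAATVCKSDLLPNTSPTSVIQGVMLLP

>pm synthetic seed profile (randomly generated, fixed)
KVKEKQNSIAGLAAGVAHPFAEAPLWSYSGTDMLNVTVVEFVSTVDLIVKISEFISRKEFRNLFRHTVLD
VYWQAIFTFTDKKSDMGIFPNREAADNFEREPDIALLKTESIQSDSTDRVITRNCRHLVPIQLTPGEAND
TYSPLFNRVLWCWEQPNEAKAGSSSDVTRGSKASGAGTID
>pz synthetic seed profile (randomly generated, fixed)
APIYHFNIGAFLFDGGEALTVWRITADVDRHSHGVYGILHSQANARAAWTYNHPVNAKESQAIQNKVAEI
YTCVSNLRPEPGVKITCKDNQLSLHLVLPKGYSLDDIRSEFTQWDYNEQISLHYAQPIKLSLYSCTEINV
FEVVETKTEV
>pro synthetic seed profile (randomly generated, fixed)
SSVGAYWWHAARKNERLAKYDPVQYLRLAAALGALRLSRFGSSEPVEGLKLSPSKAYRAHEQDKEHYIYE
SLLAVLDCEFCKAAGCTDGAFSSPNSPRLSQGYLREGYELDTASSLTVDKDEQKWWTSATNGQQRQQYDG
VAGMIQNLNTEFTYVIYLQE
>Mcp synthetic seed profile (randomly generated, fixed)
LGEPALGMCLMRDPGPISPQGTPSVEKATKIGIVINSCNVAFVGGLTSKVAESLPSGVTEQSDWSYGNEL
AGEAMFKLSKVKYAKTCQALLTNSTGTSNALKQQNTVCSIAQEGTRLGGVYSMPRLCSWHKKPESGEKPS
SGERRQFAGQPKMYNDHSRGFCYAKMAEKVEIVPLVNAGAPGEVTCTLPISLVQGAVPRSASAADGDSPY
RGKYNKIEILRVSTKFQLPNGDKFACCTETTGSVYFSNNLALLESQLPEDGALNHLFIGGTFSCSTIEIS
MKLVEQDEPSVHEITDDTSA
>pw synthetic seed profile (randomly generated, fixed)
EFRPNEGDQGWEQQRYQDASVSNRALSVEADLDLGVPSTIPIENVDTFQHKVEQGYGFQEFEQQYIAVSN
AASLWAPNKMGDTEAWLHEKKKMGHGWMQALPKPAITLEANPVLKREVGLGDCVALECINCPKAHSHFHA
QEQNRPDCIFKSKEVSWYLPLEQKGEPLHNILDSTAPPGVFVGRRQVEIGAGLLHHSAQQ
>mcp synthetic seed profile (randomly generated, fixed)
SKGLFGSFEQGQLDEVLLIDASTCINARRRTTDGCVMALYDGPLNSNAGACRALETMSVSTQTSAYNDLS
LITCDKMTKGISEAEATLGVAVEAEMDCETKFITGGLKVGAKFDVNPAEDSAILVGTCWETNTLAFRDEH
QILLSKDGAFAAGSARRTPERHSESAVLMAEIQKGGNLQDAMTWGWSFQHGAHTDRGSGPAIKQGRWMFK
ALDREVKDFGVLVSTQAPLLSPSNDEIRKGFYEQTPTRPDGGEGAIAWLSYAIYSASFWESPRPSANSQG
TRARRETELLGAMAFSVRAHRLAFGHHRLGVAGHLIYGFPVEGSAPLAGSGIPHPPGPWHPPFRKVAGIE
AQSRTFLNGIGLACSLDKQPEPVTVSTLKNFEGTNKIIKSAWRNVNETQVANMYIQWILRPESESARWVL
NRVQRPPIPKHSVLQPFDEIVVLMCSIQGI
>int synthetic seed profile (randomly generated, fixed)
ASRHDVALVEGRSYGVKPFKADPEPSNEGTPYSGQTYLASLGGAVASSYDQLTAGFADKALNVRDFAFSI
KGSWALTTGKIKMLTEIMKATPSAVEETLGGKEFMAEESTAAGDDKKHRGWFEEDHDPGAVLALHAIALI
NSNFRDTRFGGVPKTFSEFYAFGVLSACGDFNGSAVALEEWWPMLPDKGCEIGEMGPWLTDLPDGLEVNW
RTASDVVGSLGYEEPDLQGLSGDWLSKFKTFIQPCRLATWTIGPFLIFSAVTRLGDNRSLRGHELNKATE
ITNVDAKIPSHSSAIMQKDLAEGITGPWSETQTANAGFRLGRSMHKESAQWKDIDIRVTYRGSVETPLKP

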