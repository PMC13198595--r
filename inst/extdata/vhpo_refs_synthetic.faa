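>1UP8 group=1 organism=Corallina_pilulifera synthetic=true
MMSGYRGKMENFSMLHPRATKQIKMGSFGHIYQDGKCNNCGTPLTAIFNELFVSLVGLNV
EAFAKMPEFSNHCWLLYKRQQLAHHDWFGPVEKVYSTEATFLRSYALAYKPYRIWRPHHY
KICLAVWTVRWSMKEMSIMIAPVPNNADERFEPVEHWSCINNHFAQNCQFHVSNSAYAWA
ETNWKFASQHRHMKKSAIWLPMPCDPIFHDQAILKRNRHCIYLSLMVFKHRYQRDTVQLA
NANDPTVTGYYSELQMGSMERLPRVHCEDKTDARDIPNHHWKIKTWQHSFDEGIQCCYNY
LDTLRLAASHDVMQEKYMSDDLGAAANNQKRLDRMINSNWTEGPHKHANFWCYMGWNTRA
HIKVSYKQPVMQFVKRHEWFCRSKDLIIRKVYWNCLCHWFKEPWMLEGFHHNRHRNKHCY
PNSCAIQDDCGDLKYRPSQSMAYKVKHFDPHFELLHQDCTIKANVPWVKSDIYETYLYTR
SHCWFHTKKKRNHSHIWKDEPMYTLCCIITMWKVKIPLCADKDAPPNLSRLCHGEYNWPM
DWSTPSRRQA
>5LPC group=1 organism=Acaryochloris_marina synthetic=true
MRSSYRGKMENFSMVHPNAHSMIKMGEFGHIYQDMKCNNCGTPCTAIFNELFVSLVGLNV
EAFAKVPRFENHCWLLYKHQQLAHTDWFGHTTKVYSTEFTYLRSYALAYKPYRWWRPHHY
KICLAVWTVRWSMVEMSIMIAPVPNNADECFRPWEHWSRINNHFAQNVQDHVSNHAYAWA
ETVWKFASQDRSMKKSAIWLPMPCDPIFHDQAILKRNRHCIYLSLMVFKHRYQRDTVQLA
NGNVPTVGGYYSELQMGTMEALPYNHSEDKTDAMDIPNHHWKIKKWQHSFDEWIQCCYNY
HDTPRLAARHDVMQEKYMSDDLGAAAINQKVLDRYLNSNWTHGPHEHANFWCRMGWNTRA
HEKVSYKYPVMQFVKRHEWFCRSKDLIIRKVYWNCCIHWLKCPWMLEGAHHNRHREKHCR
PNSCAIQDPCGDLKYRPSQSMAYKVKHTDPHFERLHQDCTIKANVPWVKSPIYETYLYTR
CMCWSHTKVKRNNSHIWKPEPMYTLCCIGTMWKVKCPLCADKDAPPNRSPLPHGDYNWPM
PWNTISRNQA
>5AA6 group=1 organism=Ascophyllum_nodosum synthetic=true
MMSGGRGKMEYFSMLHSDATKQIKMGSFGHIYQDGKCNNAGEPLTAIFNELFVSLVNLNV
ELFAKLPEFHNHCWLLYKRQQLAHHDWFGPVEKVYHTWATMSRSLALAYKPYRIWRPHHW
KICLAVWTVRWSMKEMSIMLAPVPENADERFEPVEAWSCRNNHFAQNCQFHVSNSYPAWA
ETMWNFASQHRHSKKSAIWDVMPCDPIFHDQAILKINMHCIYHSLMCFKHRYQRDTVQLA
NANDPTTTGYYCELQMGSMERFPRVHVMDKTDRRDIPNHHWKIKQWQHTFDEGIQCCYAY
LDFLELARSHDVMLEKYMSLDKGAAANNQKRCDRMINSNWTEGPHKHANFWCYMGWNTRA
DVDVSYKQSVMDFVKRHYWFQASKDLKIRKVYWNCLCPWFREPWMLEGFHKNRCRNKHCY
PNSCACQMDCMDLKTRPSQSMWYKHKHSDPHFPLLHQDCTIKANVPWPKSDIYETYLYTR
SHCWFHSKKKRRHSHIWDDEHMYTLPCIFTMWQVKIDLCVDKDAVPFLSRLCHGEYKWPM
CWSTPSRRQA
>4CIT group=2 organism=Zobellia_galactanivorans synthetic=true
MEVVFVLSIMHQKERRNDGFPHYNSTWKKWLWMDHNHMYHVYDFAPNIYHNWIHCAHSGK
TIVLFYDHNWMTHWTWHRIMNLGVAGAMCLTEHGMIIFAAPPVKCVFQMGYQSAFAFPYE
DCHMDILFQWRERMCDKTDTYGAMWFTPAHRCKRCGCVVFPHAAGQCDASHENKIIHCNC
QTPHHEVHHQEKRWDIQGEWPNFTFQLDEKIGQHQWHHNHRYLSAQLIVVKVGVHGIFDH
SMGAHWYESKYDRRYVISVVDSADSVIGWMNQDVYHWDLKPINLECDWGMLHIPKKVGTW
ALMDAHLRRDWGSSPNNCHHEMYNRVFMAGKWMESFNMSSLKAFCACTAQFYKHSVDTTI
SPKMTNRAWPKFRKWRFPVGQLAWQGTSIRVAVSGHWLRKVHTYIYWILGWSTVHACRPV
NFCQECCDEETTCMNVFWFWQQMKCLWQNE
>1IDQ group=3 organism=Curvularia_inaequalis synthetic=true
MCASQGVSKYRVVCMYDWQKWTMCADTCGVTHSCWAKVALNIVPDVDPVEAKQPTNNADM
EYIPRSPTVPACALCLIEPYMWYKCRFMQLQAFDKICNSLMGIGTCWLQVAMYCLTGYQV
FGQVWSGRERQGHHKIQCYKACLYRDKWLCSCNLITNFWTDILNCEINWDSLESRFCILM
NNCRAFLMCINCKALKCIHFQLQNPGEIFVETMTHCLKTMLMNAIFKCSNQRLKSWTVSF
KIFYYLARSLVMTNVFEANFHNEVQKLPCWMRLEQVLCKCWDQPRMHGDCFNNEGPTQLL
GVSKLNDDHPDPKSWDDCHASGNPFSGYIWTRMAVKYTHYMYNAHRDNHKCVYRDVISEG
WIMIQKTAHYNYECFEYWFKSSAYNDWMFIMLTGNCHFKDWTEYNSQQAECNDERQFCAK
VFTMIYKCLEPCMGCGHMVHNQCGRERGHWPSWSCWIFIRFVVSKPVVPPDLGEHYLQRP
YETALDMKWSGMSGLHGAHAWIACTHVIGGTDDAKWWYGRFNWAQHGGKKLSYCVEPNHD
FPDYQCYVMINFIRTPGRPGRPIAPTDNWGTQVGQAWSTMLQHCQISYTDKHVYTHSHCI
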