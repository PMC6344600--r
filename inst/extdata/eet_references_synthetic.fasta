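>MtrA_syn
MKRLLAVLLAVFALMAFDDNEDVQAFLTTWSASCAECHPVEIRMERWMVTGAEVVQVDQFMFYNNISRKWTATGWNQTQQNNTGYAPVYIERSGSFDCWYCHCQWIAVPSGGKESSYRDWICPIAAEFNAFIEFNLATAMPLSLKWFYYLAINTVLCSYCHDNNSQVTITTCRICHLKFKFVLNVRTVWFVADAASQDNMFSNPSCYTCHGKNASFDMTTFWRAPLIPIDYYQFETPWKDAGQTAKNNCEDCHMSICSRCHWVVQWCFMCHDEYYASDPRFQRERGCRYCHPLVCVVCHPNDCPSRTWWLKDMPWDMVSV
>MtrB_syn
QVDMTFFDRFQEYIPAWGDTYPSGGEWIKKMNLNTAEFDGIVRFEQGERVLLWWPYGKLYNKKVADTLFIFYYPAKGYPNITTGWRPVSMERNPEVFMIVQVAIYYYLSEPINNKEMESFYMQDFTTDSQEYWQTIAKEMPDWWLFYRNPSIAAAQDNRIMQARGLLDNPGMIANSPFVKAYGNGMNTMPGEDIDELAPARKMQSPFRSWYYYGSMKNQMPRFHVMQTMRPRYQDSYFWESVPQLTLFVPQRFDFWAWWNKAQEPLQWDNFTGDARREIMIAGCNNPLETQQIKMMFIVNESANLMETAQIQKRKWMDEMPYQMFEVPPTFSFGFLRWTIPLRTQMEGKW
>MtrC_syn
MKRLLAVLLAVFALMAIKNKRYWMLNTLIPRLAAMPVRGWTFPSKIFTKLVFMQRTKSPWCQLCHKKGDWSTEKERGSFPERVDWLQMAKGEQMLEQWCLYCHSQDAMQIIIEICINCHPIWMMLTWAECIMCHWPVCAQGQIKAKAIGPRCKECHNNFFQYRIIFTILLQDNMYDDDRKPSYPAPPDESIDLDVIIFKGIKRWGAFWAKYNYNSGLGPVDEVAPPKMNEDIDWITTGSVVNILVTLWEWEDWWECNNCHLPARGCLPCHQLRNLKFKKSMEPMFVGARGRWSDCFGCHKGVQPLNTYVIIIGYKVGSQPWCYQCHQVTTHTPYAPRRPIWKGDENGNGPNSDDNENTNYENAPGQARYQMDLAVSWDIYDYSYDAIERCYNCHYPQYIV
>MtoA_syn
MKRLLAVLLAVFALMAYFNICGICHNFTLNIVAYYAKVIAPLGDPCWPCHWHIAPVECRECHSVNTNFISEICYQCHEIMCPCRKCHAGKWRFVAIRQCGRCHKTIPVDWTRTNWMEACMQCHRWNSNIIRVAMQTPTCIGLEYISMYNGQEEIDNMKVGRSANSELWFNMVACSSCHYLGSDDKGYFAQPMKQRKWFGGLWGPVGRLRGQHHTNMGSAMKLKWTQTQEFPGMWTKEGTCYRCHKFIVIYLICGMCHKKPKADEWPRGVYGVCRAKRAILLVISDSMRYAYILNTNQQIEIARKKETVTNRLGQYKQELW
>MtoB_syn
NANWSYDMNIGTFKTRDKEEERPSRFTTRIWYNINLPISKFPALSFNWTLMSAALEYREEKGFYFITWYRRWKENWRASMVEKYMVPRSAPLSLYRPPHYEWWTQQFVGTIWVDDVGGFPRLQMNARSNEWWSDWKAFAGQYIWGDVFWSNWMVFAPHQPNTLDMLYYEGVSKKNFVFNFGTFDNFWSVWYADQEFMDGYVLEFQYMSIYGWADRQCGVNSATDQLVDIWTSFMGEYTTKVETRNDADSAQTQNLPEMSGKTAAAANFARMEAWSNESWGKAVYTGRATVARVIEYNPPYQYAEFFKRPELYIYMGKRPWSEQKTIFIFNKFSLSYTQAGNKWMNKIATY
>PioA_syn
MKRLLAVLLAVFALMALMQWEYARARPDCTNCHKFGDPQDSGFSYNAITKMNFNINYMMTDARWAPVIWRIVVPSAVFWLSGISSPIEVREDVKWNGAQSPPEYGNGQCDECHTSLMWDLQRVFGMDDPMMCSMCHKRLDCPWCHPFVLCWGCHFVMGTDPSLQAKSNKENFEIWVLQGIIRDCADCHSIRWLKLLNFKNRLNVNEPCGDCHGSQWKSRETPMNSRGITCKPCHAWHYCYRCHDGWRLPEYITQFFFISVFRKYIFYWWDRNDVMWAYRWAGIILQWRLINLCGPCHWQQTIKNPWVYIDLDGLQGKTVREGYMQAAATY
>PioB_syn
KIPLMYGNKIGNRFSITFLFMQSFTSPFLMEWFTPRYPLSQWPRDDQDMSGQGKNKPYNPKRRRWNHDAEWQPWQTEPGFETLNVDGKKLLDNQQSTEMMRTAPPWTINGAFEVVGLQNLFFVELQAKTFILIFFGINQQVTRYEPRYAYKDQIFDYEYFLPIEWSKIKIGNINFTWSPVYTEMGIEGDEREYTSFRQWQFVVKLFMAKQGYTDFTVPQPNDYYSYWDYMVMGPTATDWRGITARFMSRNMYNHEMDEMSFATRKIDWLMQDDNNPIKAFPFGPVMIFNSAWMSCKEREMIYAGYSCGDAAMIKEKDRELINDQNGGQNIGFKVRAFQMVQTNAYPNSGT
>OmaB_syn
MKRLLAVLLAVFALMARKLTPNCPRCHPMFPQMWAIQQIYRVDRLRGAETSDAIVQELAIELCLFCHIKRGATTFADMDERYLMFDRQQRQKFWIIKLWWQDLWYMYWEMKNNSIQPCAWCHEQYTCLKCHGFMEINFLLLVREPMVCIWCHRIYAPSCRLCHNAESFPTQIKQQAVLQVAGCEECHTVVPVPSSLQSVDHGQNTFDESYVPLMVYPSRRWHWDYDAYWQEVPQSLTCGECHPWEQMQINLWLQQMEEDSWFNQAINKQVSLAYFKQQSDMMFMIDKTMMGYKPVKTFWW
>OmbB_syn
FDDYRATVFSLKVIKYRQCYFQQYMFMPDMFKVANMAKNPQTGNAANHERVLSVRTLFRAHLLDDPFEPNEKDNSRKQFGMQKGWQRGWPRPIAKGLSTYLAPGIAAEQTPIFEHWTHTDDYLYKSIAPEKDKQYYSNFNSVDRNALYIYAELAFPIDKMKKSTLLDTAAAQPLVLNWLDNLPKTYMRFGYNAPADGFVYKQRTEYKRFIEFEIDKEPLPASQTEKGYICAKARWRDRPISIEYIVLVSMGREQVGPSVYNFAMTWQLMRDEFTKARYRDYWKTSIANAVMGQYNVYSLSMPEMRSTYEYIWPTKFESWRKATPVMTKKFMYTMSQHGGGRVMETTNSNNFHWRYQYLEA
>OmcB_syn
MKRLLAVLLAVFALMAWQFVEWDDQLVVANFAPEAYSARKDTTCTICHVSFYVMLGQRHYQEYVENLSNIYMNRGENLFLLVRIYKNSCYTCHQVCYACHQITGNQGYSYQMDRNYSELTGNYCQKCHRLGYFVNIKQTGFPTCVICHVEEAYVIKNWFSNGQPCVRCHIYMNWLFYLTSEDIFTMDVFTEQRVWSYFWDFNEVTPRNDYLWLMACWICHDGQMVIWRRSDRDTNFWVSEDLTGKMGMYFDYKATSTFCSRCHTTANQHWETYGMGSDWTWIKRWPCQQCHVWVQIEMQKSCFNCHVAKKGQKNIVEAFTPLGVMLDAYWKSNTAMIEVVSGYMTACQECHLQTWASTKRIKKFSYMWSGCTYCHDYGIP
>OmcE_syn
MKRLLAVLLAVFALMAWSELTVVKLCYQCHFWAEVNWFWPVCTLCHPQPIARVRRYELMEEKAFWSTSMWDQKMSPELVMATETLTWFEQWQNRMNQPIVQLEPWTCVKCHMIRHVLKAVQEGPMCSMCHMDWCESLAMRDYTGINVAWPGYKIAIKMAGYECKREIVNIHWYWQGNIQRIDFAGLITRQDQKGTAIMTP
>OmcS_syn
MKRLLAVLLAVFALMAGTIRKAVLFAITGYFNISEPVEHWFKGPWYPLYQANQPGAMSYFPMWIGTWAVNAFWLLCTDCHEAAKAEIITRILIFQAHRYKASLQCFMCHLVNGRPHSWQAKMAVGPRLVKVFWCLTCHMMVKRECQMCHRLSKAFMVVNSVTEETAYDMTIINWFFTCPPCHTGLQFKQMGFDRDWCSWCHNWSQYGRSRRPQFLMMVSL
>OmcZ_syn
MKRLLAVLLAVFALMASLSYFQIQSLGNQQFRTCEICHLPAQIQMSYLILVNQTNKLMFGKRNLIRVIGGNEADNMETEMAVNPKVRFVYSYDQKLQKTWKYAGYSNMMDIFFAWRCRTCHAVQMWQVTRMEMATFGICVQCHVPAELPTFKGGCRYCHPKIWYPFPFSKPCWPCHIWKIANCWVCHMPWGFVYNSYMPAGCQLCHIYVKKLMRPEPVMATARCMGCHYARQKETAIFGKASGQGWSQFKFYNNQIQRHP
>Cyc2_syn
MKRLLAVLLAVFALMAGELWIYCTECHWPWMIDFASLLTRMVYRMPPKKGGIVFDFQFRYSLNMQRGMFESRRFFYGTWVNTSYFDPNETYFTVMKEKYVAATSAAKVIGGPAMVMSVWDTFMIRKWRGNYNKSMMFNQAMSGVSVGFRPVAIHPEYRLFDIKLQWWKQGARAQGMGTMDVAFRFVKGDFLPMWLSYRGRGMTMLYMNNLVGKLEFKFLFENGQHWWQDGPDRSYWKEMSSFEEKVLLFREAIVGDRQYGRFNLRAKHLGMVLGPVKGIWHMIDDGYENKQNTAPDTYWSDDTFCSMMGDWQEINPFVMEWLFYPWSRWGMFNRLWFPSTRMMRVPPEEWVTTSYSSIQLYSYRGTKWVQPEWLKGDPAYRIQSAFREITQSDGLDTPHKLIKGTKFWNTDKVRPRVFIYERFWIIYVPNTKMGSSSGRVIKTIFLKNQD
>porin_other_syn
ETFANLIEAWGRLPWYQCPTAYDFETYFVLQYSTNIIGGQEGAYPQIGNIWQYRNSGQKHTYPSEYFFPMWPDMEGELKDYVYEWWYGKRDFWRYTVIIRNHPDELPAFAVLAAAVFQFLACKGQAYDMRYVSVWSAMSGPNKLYYESNEWPAYRRSPFVFEIKVETRINNIDSYTGKIAILYDDGPSEDEMDRYWGDNWATIRYTMGVSRDDMLTFEWKKPKPLTRSEQWWDQTVSNYSKMYVGGYPQAIDRTGQNSPKPPDYKKAYERHISYDDDSRRIERSGGKNETYATFETFRVEVGVESYYSKYYPGKAPDNSTQEIDYNSEIIQFERWRWWRF
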