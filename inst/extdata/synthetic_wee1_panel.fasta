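>HsWEE1_synth [species=Homo sapiens] [accession=synthetic]
SLFTVIQRQVRGDPWIRQHPQYVCTDYQMPIHFTYPVKTYDYRDMNWTEFKQKRGDFRVP
TKRFTEWYIIMHADACHLSRAATCAALYDRMEFFIDYIMTVMDQSGFMRTDMSCLWRVFD
CSCARDRVPAEDHHMLQSQSRMKNLFGPMGIQSHPYKQKYRTTQIIYPSGADWNFMMADK
DWMEWEEATTERWWSDFYSWELQVPDHVFHDVCIKFACDKNKWFWNEMWSPFIWCQPYME
ELGHNGMAFVYRHTSPLQQSPWFQSNQNMSHLGAPYEQDFYPSQMGSEMWGMNAQQSYAM
TKGSGEFGEVFKYQQAHHYAPFEVVAIKVIWLMLYTKEPRMRSLTYNMIRSRHVIQKQDH
SDYNFIRVSAAPREFNALCDLCWHLNLAATIPSMNGAIARPWTYSHTFREPYCLENEYWC
DIVHRDLKPENILGMVQRFEQTDRMRRMMRAQHPFTLRKGSIDLGGMQWINGYSLIEGDY
RHHFTLEKQPDNKAFYQKGWDMFWRSLVFMRWLHRGLRQPTNVRQLHAYLNNFESSWSSI
DMLHDAWTPRCPASEQDCPLWILGGFASVIMQCCIKKEVPLKPRDHKWSCWGKTIKTTRE
LFVAIDQSHFALSKRPTLANPCAILRGGISSYRYGCHMEKAATVRL
>AtWEE1_synth [species=Arabidopsis thaliana] [accession=synthetic]
LFKRHFFLVDTKLMLEYHIIQGHWMIHRVRARTHTRTFNHMEKFIDGIGTFHDMSGWRYT
QSLWLDYEGQVLAMRPWFPKETHWGLQEATRNSNGIGIMKIWMPWWWIKYNIFTIDYPIT
RYWICMMWNCFWMAWSERKNNIWWQDGINGLQHVPKGVCQSVFIDYACQKNKQFQNEDRS
SFQCCQPEMHRTNHNSMAFVYFMENVLYQEPWIMHNPNWSNLGYSTLQDAIPDAGVSEHW
GMNAQQGIHATKGSGEFGHVFKHQNAAHYGPFYMVAIKVIWLMLHNVRPICQRLTYWFIT
EGVVIQKQYFASPAFIIPSAHPREFMALCDLCNQLNLAHNLPGMCLAKPCPPIYSHCPRE
WMDAENFYWDRIVHRDLKPENILGMDHHNEPCLRMDMMVCMQGPACQRKGSIDLGGMQWI
NSDSLIEGDYRHHFTCCHQPRHKNFKQKTKRYPERILVMMVWLHRGLEQPTKLHYSHAES
LFPSNVDSNKDMYGIWVAWRCIPRDQWEPLWINAGALSGIMCQYEKFMHPRRPVYNRLHC
WGGTMKTFYWFNLAIFQFLMALNGRSTDHDSSAQTTGLLSMDKYGCHMEPAKTRLL
>MtWEE1_synth [species=Medicago truncatula] [accession=synthetic]
FSWCEFKNFMHDDTVHLSLSATLTALDTPIENFEMYIRRVHRQSTPSRRKMSSQARSQHE
ACSSDKDDHNNRFLLPWTARMSILSQHDGIIEAPAKFKYRTTINIIPTTEDWNWMMAPHL
YLEWHGATCEQWWPSFYGWSTQNAVHVFHHVCGKDADSKSGDFGNRMWGRFDWIQPEMAA
LEHTGMYGKERPSSPLPWSSWSSGNENWAHLCAVYEQDDGLQCIISNEVQHNTQQIYAVT
LGIMEFGYVFKYWQAHHLWPMYVVAIKVIWLKGDTPMPQWGSLTRQMIRSVPSVQFWKRY
RYAFYYFEAAHREFMALCDLCEHHNLMRTYPSMMGDCSVKWLGPKMTMCGPWLCEKRFDL
IVHRDLKPENILGRIWRSYQTHAMRKMMMAMKGNTHQKGSIDLGGMQVPNGDSLIEGDYR
HHFDIEKWQHLFIKAQHGTDCICRSEVSWVCLTRGLEQPTWPRHLHDDKNNRESLKSLRI
MKHCAHTSKCVHKQQKPPLWIMQGCNRRVMYQCIALVWHLYPHDHWQPCWCMTGHRFDEN
FRGSNMYQTVWLARPQLPNPKACCRGPHISMRWTCLEHISLSSIL
>PsWEE1_synth [species=Pisum sativum] [accession=synthetic]
RMDFRRERPLWDNNFIAFFQDMWILYLHATCNKLMKAFNPIIDCPDTVMDQSGFVHTYDS
CNWDTRECSCWEMIWFRTDAVMYQCQPMMKRVRGQKGNCLHPLGPKVTTPHIIFFSGHDW
SFMVYTKMMMDRLEMSTYRMWSEYYYNEYQRPTLVFHWMLIVPSNDGNKIMWNTMWSYLI
WCDGMCWELGHFGMRFYRYGTVNWQCIICVVVIQNGHFWGCPYVQDNYWDSPHYEEEGDN
LQQMDDMFKQCGEFGNVFKYTYAWHQEFTNTVAIKVIWLMFNTLGEFMASLPMNMIRSCH
KIFLYYHSDYCFRNGWLDAREFMALCDLCKWECLAATIWYHRAIIGRSWLSQVTRRFATM
MEQGFWSDIVHRDLKPENILGMVNHHRNTYRHRRFMEAQRKIWLKVGSIDLGGMQAIRFS
SLIEGDYRHHFDYCKQPPNFIKNSSQNTFCWVSCWFMRKYCRGLEQPTLEHDEHAYYWAF
EGMWEMIDRAVDAWTPMPPLNEGVCGAWILRPGCIVIACCGCKKEVLKVMRNHMWGTWRI
IWRTTRWLDVAIPCSHDYRYKRNTSCNFCAKWQRGILPVRQGWHSWKQIESYY
>VuWEE1_Chr6.1_synth [species=Vigna unguiculata] [accession=synthetic]
WRSEVTFRTTETYSIMHADRCHLWRHATKAANGVWMACHFYYIKMFTIFSGFMRGHDASS
WRAFDKVGANACLIQMCHYMMLEWSREKVKRGQRMIPEYENDTKQIMWQIIIFSGASETF
MMKDKKKSWWENAHTTMWIQDPYATQHYTRCHHFHCVYFEFGCDDNKWFNKEMYSPFIPK
QPRHQKLFHWGFSFVDHGTSETTQVPWFIKFQNRSPLNPPCEQYKYRFCTGLVNGGMAAC
WKYHFTKNYIEFGSVFKTQQDDIPAEKEIVAIKVIWGMKGTQMHTMFSDTYNVIDSRHPS
EYKIHCDDNTCRVSPSIREFMALCDLCFSIDFGRYIPSMLCAIVYPLTYSATTRCPLVTS
GHYQHGIVHRNLKPENILGRVCRFEATTVHIRWMRMQHCIIERGGSIGLGGMQLFNTYSL
IAGDYSHHFTRYKMCEEHAFYKKGWDMFWCSLVWMFWLHRGLEQPTRVFRLHSYLNHHVS
DWFIAVMCMDAETIMHLADIEPYFLWIEGGPASDIKQNCQMKSDNLKPRDHKWSHKFHTI
HTGRKCFLAGHQSAFAHSKGPWMWNLLCSGQGCGCGHTYFCRTEKPTTHRN
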