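>synth0001
AFMSWKQRNISHFIVCFGGVIKNYWSFIKLMSSSNPCLRNFMKEICGEYRDNQKVGHECQ
MHWE
>synth0002
WWPDVDSLEHDVEPAQTFWRLKKNSNEDCQMSERDFMDFLSITPHKWKYRQMQLSYWATT
YTPYHDRVRKNVDKQTNKVEAYE
>synth0003
INLQPFWFMEGTVWNDTAFNNCCEDETQIYLALWACYECQWACCVKGMWLSKKDKNNEYK
MARGIMYYCQTFLIQMCPSMWHMHTTIPLG
>synth0004
WPFIYRVFPMCIDQHVCFDVHMTEQLHIDEHFDYMIPLLNPVWKIQMWWFFEANCPPYGF
KYWPTPMEKC
>synth0005
RKMRTACMKQDHINTRRDTKDQEYCHQRQPYNTDYPAPVEWPPAFGQEQNKNYEEHSEDN
MPKAKCSVKGSKEGSWYVHWQRHKGCHRAIVLDSVTPYFVTWLITFHIEKDGKYKRWRVA
VQIQPY
>synth0006
CQNKCKQRYSWVMGQERNLEQEIPWWWHDHQASHEYQFQDFTMTKIPLRNLVIEKRAIIC
YEEMACLPFSWKTMPDVWSQTLTLQCMLMYTYMFNRGPIPPHWRFST
>synth0007
HAISNLLVWCESWMNLTAREYRARRGCSITAHNRMCYIVEAFVARVGCQQPSKYSRIPYH
TFLMVR
>synth0008
RAHNYTWAHGRCPGEYMILWRYCWEWFYWDSGRTKTDQSYPYHCSAHRGVGHPCSMDSMK
QSGKPHCYAEEEQRWDFQFTVPPPSLGVIQFIGSHPNYTQHPEVDRNQAGTNWDDCQVMG
LYMIKAQKE
>synth0009
MAYFRQCLMMHCLTTQAMVEGPHSWMDRHWGQRQHERTYQKAHIRPHDLEIMTFEGVGCN
LFRNGIWVRW
>synth0010
CMDFICFEMSQVNELSAYSLLRRINAQQLLEPRWPVPGPVFYDVFNENSILDWWNEITRM
RHQIHNIRCKRTFGRNWRPNKLYHRREKMASLWRVGEICWYDYPSLT
>synth0011
PYQTKAVFNYEGGNVGVVTPKNRDRYVTWWRYPKTNWCGYVGELEGEKDYRYKMILWARL
FLALDDTC
>synth0012
PCRMDFLCAQEMMGFPPRCLHQIWVDYTDQNAFTYFFTADGLRKWTLRMIARKAPKHCGR
YPMITFKHFAIACGEWPSTSHAGPGWEKSTYWWNQMMYGYCVPQTQQCWFLGQLMKSGGP
WELYMDGVYRPK
>synth0013
GHTCFLENWKDHHMLMRHNTGQASWWIDKLMQIHASITDCWIQILHVLKTCTWVKQEGPD
NFWYKTRDKVWVSEDAQSYEAMNGQGITYL
>synth0014
MYRDDLRPMCGCFGEPRYCMVELEELLEAQISLAKHIYAGPGTCSYTAHCKPWLEDCFGL
FPKPMETTARTVQGHSNYMPKQTFFQDIGVVLWNAQMTNHRNKLVRKQEDELWSVLAWDD
MTHCMWDCCLGHMV
>synth0015
HRYRVKWSQEGEQHMYFHVGLAEHRKDTEANFGNEDNNDKTPVVNPEWGLKAREFHDARM
FIMHIECQAVVQWFEDIVPDICENTSCEEKTFYHDINEFMWANTGGTDDAWEDILWQIAH
SGGPQ
>synth0016
MWCVCKINSFMQWDECPAEYMDAQEAPCMCKHFHWMFSINPWCAYHDLQGEEWYYCKWWP
LISDLGLRAMAIKMGKRYGERWWDEIKQQAMVKKHKPACDYKPARMMHASPFLHA
>synth0017
TRMGPKTPIIAPSNDHFFIDHWETSEKPLGHFIIKVDYKIAGSGAHKDNNQADVWERYGH
EPETNMAHKKLERDFGSKASEWQELVGITPNVSTIVNAQYCPNFAHWAVVDWPLIDCKAM
FLINCKYTENHLFNESKW
>synth0018
WEACYHFVCKQYTETMLIWGRRIQEEEPWYMWFYKCYECWAHSDENPFPFVFQAPPVVMP
IIARDDSEYERNRTTDDMMEIPPFNPWIAPWIGITSNFLCNEGQLNEHAWMIL
>synth0019
NFKWQIMLCFFIWANYEWWQGLWHHMIRMKYLWQNRNACCCFTPPHWDRVMNYVWFEGHW
FQDFNNCGAYGIENWCYFRPPGSQTTFQKEPYPGFPHFIQPYKCHMTSGRNMMWVDAYFA
NFEWY
>synth0020
YEEIHPQVTILIEAGNAWPPDKGNTTMWEEWTVKNNWHCRYCAAKERNFTADTQFQPNQP
NLRDYKEWREYTCEKGPRAYFWVR
>synth0021
AWAHFVQHFGMVCWRSDGGCVMSVWWTMCWAMIGSDSWCKCNRTPCQDCVPPETHYHVME
NNWANLKRLGDTFCHKGDLQNGQSGVRMHPKVSVAPQEYDTEKHVRRFEIPHALANEQCY
HMRDMHPGPVEQLGFFESM
>synth0022
WKWMIYYFDECGEVGDIEKRRRKYWKCHKYARERQRGYVERPWPKECNIYIEMVYWEERT
QEIVGWQWTGCHAILFLPTDRKETLEYEGWWPHCCKMPMW
>synth0023
QIMFFPKYIHWHHDYCPLAPVFVRAVMNNNLPMINDEGATSSADKWCFNGFGKDVKKQRM
ACWSGHTVPCWRGWLQRGNAEQYSLICDPLQWVWKMPQTQNHTADECVTCTKCLGFFGVM
SDAPRELSNE
>synth0024
SHPWTRWYWACEESWEHFMPHTLESQKHHCLCQPISIVGIAISMENEWKFGEAHKEPCCF
CKRG
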