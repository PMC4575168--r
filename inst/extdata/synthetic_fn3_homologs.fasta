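>synthetic_homolog_001
FSDSPRNLETTNATPNSLTISWEAPA-TVRYNRITYGETG-TSPSQMFTVHGSKHTAFISGDPPGHDY-ITVYLVTIRGTSPASSKPISIMY-T
>synthetic_homolog_002
SSDHPRNLEVTNA-PASLVISWDAPAVTVRWYRPTYGETGGNSPSQEFTYPGSKSTWTISGL-PGQDYTITVYAVTGRGDSPGSMKPMSINYRT
>synthetic_homolog_003
SSRSPRNKEVTIATCNQLTICFDAPAVTVRYYRITYGEFGGNSP-QEFTVPGSKSTATISGLRRGQDYTIQVYAVTGRGDSPDSST-ISIN-R-
>synthetic_homolog_004
SYDSPRNLEVTNATPNSLTITWTAPATTKRYYRITYGHTDGNSPSQEFTVPVEKSTAYISGL-PGLF-T-TVYAVTARGDVMESPCPISINYRT
>synthetic_homolog_005
AR-FPQNEEVCNNTMNSLTPSWDFPAAMRRYYRITYGETMGNSPSQGFTAPLSTST-TISGLKPGQDYAITQY-ETGRIDSFWSYAPISIQYRT
>synthetic_homolog_006
SSKNPR-SEVTNATPMSLT-SWDAPMVTVRYYDITYGETGGASESQEFTVHGSKSTANISGLKPGQDYTITVYT-TGMGDSAASSKPICIESRQ
>synthetic_homolog_007
SSISGRNL--TNATPILLTIF-DAGAVTVRYCRITYGCTGGNQTSQEFTNPGSK-TWTI-GLKPGQCYPITTYAVTGRGWSPASSKPISTNYRT
>synthetic_homolog_008
DSDIPRNLEVTNATPNWLTISWDKKAVTVRYYREWYGETGGNSPSQEINVPGSKSTA-ISHLTPGQDYYIT-YA-TGRGDSPASSKPISINYRT
>synthetic_homolog_009
SFDYPRNLEVVKATVNWLTISIDAPAVTVMYYRATIGETFGNSPSQEFTFPGSKSTATIFGLKPGW-ATITWSQ-TPRSDSPASSKPISICYET
>synthetic_homolog_010
FYDSPRNLEVTGATPNSLTIQWDAPASTVRYYRVTYGETGGFSPSWEFTVPTSKGTATQSGLKPIQ-YTITVYIVNGRGDSPASSKPISINYRT
>synthetic_homolog_011
SSDSPRHWEVTN-TPNSLTISMQAPKVTVRYCRVTYGKTGGNSPSPEFTVAGSISTAPLSGLKPGQDFTIMVYAVTGRGDSPAQSKPISINTRW
>synthetic_homolog_012
SSDSPRNLH-TNATPNSLLTSW-APQVTVRFYRITYGETGGNANSQEFFIPGSKSTATISGL-PMQDYTITVYANTGRGDVPASTKPISINYRT
>synthetic_homolog_013
SSDSPRNLEVTARTPNSLTISWDA-AST-EYYSITYGETGGNSPWTEFTVPGIKSTRAISGLKPGVDYTITVTTVTGRGDSPASSKPISINYRT
>synthetic_homolog_014
SSDSPLNLLYTNAHPKSLTISWNAPAVFVRYYEITYGEVGGNSPSQEFTWPGSKMTATQSGLKPGQDYQITVYAVTGRGDSPASMKPISINYET
>synthetic_homolog_015
SSLSPRNSEVTN-TPNSLTISHKAPMVHHRYGPITY-ETDGNSPSQAFTVVGSKSRATDIGLKPGQSY-ITTYATEGRA-SPLSSKPISITARV
>synthetic_homolog_016
SSISPMNLEVTIYTPNSLTISWDNPAVTLRY-RINRGETGGNSPSQEFTVPVSKSTARISLLKPGQ-YTRTVKAVTGKGDSPASSKPLSFDYRT
>synthetic_homolog_017
SMDSPRNLEVTNATPNSLTISWDAPAVTVRYARITDKETGGNSPSQEFTVPGSKKTATISGLKPGQDYTDTVYAKYGRGDSPARPKPPSIN-RT
>synthetic_homolog_018
SSDSPPDLDGTKATINSLTISWDAPAVKVRYYRITYGETGANRP-QEFEVPGSKSTATII-HKPGQDYP-TVFAVSGRGDSPASSK-ISFNYRT
>synthetic_homolog_019
-SDFPRNLNVTNLWPNTLTISWDAPAVTVRYYRITYGETGTYDPSQEVTVPWSKSTATISGLKPGQDYHITVYAVTFRGD-PCLSKPISIN-R-
>synthetic_homolog_020
SSDSPHNLEVTVATPNSLTISSDAYA-TVRYYRITYGETGGNSPDQEFTVLDCKS-ATISGLKPGQDYTITVYMWTPRGQSPASSKPISINYRT
>synthetic_homolog_021
SNDSPLNLENTNATPN-LTISKDAP-FTVRLYRITYGET-GNSP-QEFTVPGSPSTATIWGAYPGQDYTITESA-TCRGDSRASSKPISINYRT
>synthetic_homolog_022
SSNMPRNLEVTNAT-NSLTISDDAP-VTGRYKRITYKITGYNSPSQCFTVPQEQSLATADGLYPEQDYTITVYAGTGRHCSPTSSYPISINWRY
>synthetic_homolog_023
SSDSKENEEVTNGTPNSLGISWDMPAVTVRYY-ITYGETGG-SPSFEFTVPGPKSTACESGLKPGWHYTITVAAVTGR-DSPASSKPISINYQT
>synthetic_homolog_024
SSDSCRNLEVTNATPHSLTISWDAPAVTVRHYRITQGETGGNSRSQEFTVPGSKSTCTIS-L-PGQHYWITVAACTGLGDPPASTKYISINYRT
>synthetic_homolog_025
WSFSRRNLEVTNATPNVLTISWDAPNMLTRYYRIT-GETGGNSPSQEFTVVGSKSTATISGLKPDQ-YTIRVYAVTGRGDSPASSVPISINYRT
>synthetic_homolog_026
SSD-PRNLKQRNATPNSLTISWDAPIVPVRQYRITYG-TG-PSPSQEFGVPPSK-CAFISGWPIGQDYTSTVYAVTGCGDMPAKKKPISINYIK
>synthetic_homolog_027
PSDSPLNLYVFSLHPNSLTIS-QAVAVTVRYYFITIGETGANSPSFEFTVPGSKSTVTHSGLKPGQDYTITQLAVRGRGDSPYKS-PISITDR-
>synthetic_homolog_028
FSVSAARLEKTNAT-WSLTISWLAEAVTVRCYRITPGEVGGNSRSQEFTVP-SKSDAQISGLKPGQDYVIDVYAVTF-RDSPASSKPISMNYCT
>synthetic_homolog_029
SSDSPRNLKNTNATHNSSTISWPLPAVTVRYYRITQGRTGGNFPCQEFTVMGSKSTATISGYKPGQDYTITVYHTTGRGDSPASS-PIE-NY-D
>synthetic_homolog_030
SSDLPRNLRYTNKTPNSLTISSYAPDVTVRYYRITYGETGGNSPSQEFTVPGSKSTETVSGLK-GQDYTITVNAVTGRSDTPASSKP-SINYRT
>synthetic_homolog_031
SSDSPRNVEVTNATTNSLTISDDAPYVEVRYYDIANGATGGVCPWQEFTVPGSKSTATISMLKDGQDYTITVYAV-GRGDSCASIKPISINYRF
>synthetic_homolog_032
SSDSPVNLSVTNATPNSFTIEWDA-AVTVRYY--TYGETGGNSPSQEFTVIGSESTAAISGLKPGPDYTMTVYAVTGRQDSSASSKPISINYRT
>synthetic_homolog_033
SSDSTRNTEVTIYQPNSLIISWDAPAVTVRYPRFTYGECP-NNPSNEFTRPGSKSTATP-EPHPGY-FTQCAYAVTGRG-SPAWSKPISINYRT
>synthetic_homolog_034
WSDSPRNLEV-EATPDSLTISWDAVAVQVPSWRIHYGETGGTSPAMEFTAPCSLSTATISGLKPGQDYGITV-AVTGRGDSPASSKPISANYRT
>synthetic_homolog_035
SSAIPRNLEVTKLTPNSWTRSWDAMCVKVRYY-ITTGWTWGNDPSQHFYGP-SKSTTTKSGLKCSHDYTITVSAPTGRGDSP-SSIPIS-N-RT
>synthetic_homolog_036
S-DSPCNLEVIQATPNSYTISDDAPADHVRYPI-QYGETGGNSPSQEFCVPGSKETATISGLKPGQDY-ITVNASRGDGDSPAS-KPISINYRT
>synthetic_homolog_037
SSDSPRNLEVTNATPNTLYISVDAPAPTVRYYRFTTGETG-NSPSQEFTYCVS-SWATDSGLKCMQDYLITTY-VTYRGCSPGSS-PFSINMWT
>synthetic_homolog_038
SSDWPRALEVTYPTPNSLTISWDAPAVT-GYYRWTYGEDGGHTPSCEFTVPGSKSTKTISGLKAGNDTCIAVQAVT-RGDS-ASSKPISINART
>synthetic_homolog_039
NYDSHSNLEDTNATPNSLTISMDAQVVTVR-YRITHGETGYNSPS-EKTVPGQKSTATISGLKPGTDYKITV-AVTGRGDSPLSHKPIAINYRL
>synthetic_homolog_040
SSDSDRNLNVTNATPGSLTISWDAPAVTVRYYRITGWEYGGNSPSQEFTVP-SGSTATISGLPMGQDYTITVR-VTE-GDSPALSKPISINYRT
>synthetic_homolog_041
FSDSPRNLETTNATPNSLTISWEAPA-TVRYNRITYGETG-TSPSQMFTVHGSKHTAFISGDPPGHDY-ITVYLVTIRGTSPASSKPISIMY-T
>synthetic_homolog_042
FSDSPRNLETTNATPNSLTISWEAPA-TVRYNRITYGETG-TSPSQMFTVHGSKHTAFISGDPPGHDY-ITVYLVTIRGTSPASSKPISIMY-T
>synthetic_homolog_043
FSDSPRNLETTNATPNSLTISWEAPA-TVRYNRITYGETG-TSPSQMFTVHGSKHTAFISGDPPGHDY-ITVYLVTIRGTSPASSKPISIMY-T
>synthetic_homolog_044
FSDSPRNLETTNATPNSLTISWEAPA-TVRYNRITYGETG-TSPSQMFTVHGSKHTAFISGDPPGHDY-ITVYLVTIRGTSPASSKPISIMY-T
>synthetic_homolog_045
FSDSPRNLETTNATPNSLTISWEAPA-TVRYNRITYGETG-TSPSQMFTVHGSKHTAFISGDPPGHDY-ITVYLVTIRGTSPASSKPISIMY-T
>synthetic_homolog_046
FSDSPRNLETTNATPNSLTISWEAPA-TVRYNRITYGETG-TSPSQMFTVHGSKHTAFISGDPPGHDY-ITVYLVTIRGTSPASSKPISIMY-T
>synthetic_homolog_047
FSDSPRNLETTNATPNSLTISWEAPA-TVRYNRITYGETG-TSPSQMFTVHGSKHTAFISGDPPGHDY-ITVYLVTIRGTSPASSKPISIMY-T
>synthetic_homolog_048
FSDSPRNLETTNATPNSLTISWEAPA-TVRYNRITYGETG-TSPSQMFTVHGSKHTAFISGDPPGHDY-ITVYLVTIRGTSPASSKPISIMY-T
>synthetic_homolog_049
SSDHPRNLEVTNA-PASLVISWDAPAVTVRWYRPTYGETGGNSPSQEFTYPGSKSTWTISGL-PGQDYTITVYAVTGRGDSPGSMKPMSINYRT
>synthetic_homolog_050
SSDHPRNLEVTNA-PASLVISWDAPAVTVRWYRPTYGETGGNSPSQEFTYPGSKSTWTISGL-PGQDYTITVYAVTGRGDSPGSMKPMSINYRT
>synthetic_homolog_051
SSDHPRNLEVTNA-PASLVISWDAPAVTVRWYRPTYGETGGNSPSQEFTYPGSKSTWTISGL-PGQDYTITVYAVTGRGDSPGSMKPMSINYRT
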