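>HRAS|human
MSIGGPMWPSGGGISSVDYTCEENACKISPPGYLWIKHIGRFCLLGSEHVSTIWTSAYCL
QYTHVSRTRRSRKVGFVRVPKATGRIKSTNCRRGLTGACTQSSMTLLGGSTLYIDLPANF
TAGRSMAIRHWKGNGEIQVGSGSRFDPPESCYGKRFAKDFSQRIHTRRSPTILYPWLNDR
PINRVVTPR
>HRAS|canine
MSIGGPMWPSGGGISSVDYTCEENACKISPPGYLWIKHIGRFCLLGSEHVSTIWTSAYCL
QYTHVSRTRRSRKVGFVRVPKATGRIKSTNCRRGLTGACTQSSMTLLGGSTLYIDLPANF
TAGRSMAIRHWKGNGEIQVGSGSRFDPPESCYGKRFAKDFSQRIHTRRSPTILYPWLNDR
PINRVVTPR
>KRAS|human
MGFVDALRISNGGRRYGMMLDRSFIREKSASFRTIASPGKSMMCATRPLKFASLWPSSCQ
IARIADVIKTPWACIRATPRWNLVRATVRASLLSRLIPSPVCHSFFRAKRPIHSNMTEAG
DSYVSRQQLITLSRHKNRSHYLHWQRAGLVPVKHHLGPRIVARELGLPDRHGNVLYQKPS
GSVVCGIF
>KRAS|canine
MGFVDALRISNGGRRYGMMLDRSFIREKSASFRTIASPGKSMMCATRPLKFASLWPSSCQ
IARIADVIKTPWACIRATPRWNLVRATVRASLLSRLIPSPVCHSFFRAKRPIHSNMTEAG
DSYVSRQQLITLSRHKNRSHYLHWQRAGLVPVKHHLGPRIVARELGLPDRHGNVLYQKPS
GSVVCGIF
>TP53|human
MLGLDIHNRTVHRTLVLDIMLTNRCGSEVVRACASALRMHHGGNSNDNIPSVKNAMEMLA
WGVLSRSGTKPKRRSETLCQPTYNPRELDVALVDLRHGTSLIAIVSPESVEVDTSTNLTN
HEVTIPNICILFATLRLSNEARGTGWHLFLVFLLAWEDVRAVTLAILVKIMTGAVRYIDP
GAGLDPWTLRVLVTVGAKHVAANEPLVGECRANRYRHRKGTEPHAIEQGPFVTRSGWVNL
CLSDAYFGPKFKTGPHYLLPAASWIHNCQARVLESSRVEASLPAITEEVGPGTTAYLCIL
>TP53|canine
MLGLDIHNRTVHRTLVLDIMLTNRCGSEVVRACASALRMHHGGNSNDNIPSVKNAMEMLA
WGVLSRSGTKPKRRSETLCQPTYNPRELDVALVDLRHGTSLIAIVSPESVEVDTSTNLTN
HEVTIPNICILFATLRLSNEARGTGWHLFLVFLLAWEDVRAVTLAILVKIMTGAVRYIDP
GAGLDPWTLRVLVTVGAKHVAANEPLVGECRANRYRHRKGTEPHAIEQGPFVTRSGWVNL
CLSDAYFGPKFKTGPHYLLPAASWIHNCQARVLESSRVEASLPAITEEVGPGTTAYLCIL
>EGFR|human
MICSCPLDEGRICFLIRSTRLFGIPNRAEWLHHVRANRQMDHSATRLREPPAEERRTGVS
KNMGSSFGDVAQRRWGSYRTSSSIHSGPGVLIIRCEEDLPTCRSNIGPVVASVYQQRARS
APSSVAWRRYPENVPLLIAPGHMFNATTREAVAHAQNGYSKACPRAFALVERIGARLDDG
GTSTIPLKNIFTQSPASGGNCRTWYVILAYNPKEEGRQCIEVKLPEYCCWTREFRVFVKA
AHGMQSYPRR
>EGFR|canine
MICSCPLDEGRICFLIRSTRLFGIPNRAEWLHHVRANRQMDHSATRLREPPAEERRTGVS
KNMGSSFGDVAQRRWGSYRTSSSIHSGPGVLIIRCEEDLPTCRSNIGPVVASVYQQRARS
APSSVAWRRYPENVPLLIAPGHMFNATTREAVAHAQNGYSKACPRAFALVERIGARLDDG
GTSTIPLKNIFTQSPASGGNCRTWYVILAYNPKEEGRQCIEVKLPEYCCWTREFRVFVKA
AHGMQSYPRR
>CTNNB1|human
MNSKKSVSASKCLPHELPCGLAASCKQCTRTLYGIKCYERSNSPNASICAMPKNPTLAVD
HMGNNPTDLLTVGQLTPGDLRGSAQQLIRSPRWEVLVREYRQTRPASALANLLSTHLGNN
AQANLGNSGVARLDALMELIELHWGTRSGLRERNGQHNCGQPARQANGGDFVHYTANAMS
VITRWRGGGRAVYRNSLRRAPNNRDGTSSIRLWEPQHRCVDAGQIHFHNTLNICWIRFSS
>CTNNB1|canine
MNSKKSVSASKCLPHELPCGLAASCKQCTRTLYGIKCYERSNSPNASICAMPKNPTLAVD
HMGNNPTDLLTVGQLTPGDLRGSAQQLIRSPRWEVLVREYRQTRPASALANLLSTHLGNN
AQANLGNSGVARLDALMELIELHWGTRSGLRERNGQHNCGQPARQANGGDFVHYTANAMS
VITRWRGGGRAVYRNSLRRAPNNRDGTSSIRLWEPQHRCVDAGQIHFHNTLNICWIRFSS
>BRAF|human
MVSIFEASSTGKHGRLEFSSMANNLGNEYGGLLIHQPQHRSRPWPLDGKSTHTRRSAYST
KVTCPAPLMSARASKLSPQPRCESQCRTHNRAHSLYEPGDFTFQVPTLVTVERCMEHLTP
EGSHLPCVSRQVRTLETGKGRAGTGKSPQVHGLGREDRNSRPPVLYKLRADATRMFNGDG
SLPSAFRLYAFYQNNAGNSGGASANSCKKPFALGAFRTVPMFCLWISKLAISATREHQVN
LVVGRSYTLVVYLFVGNHSCLLEQYVPTLVRLMAGFQQRIIMDFHVARYIERAGLTSTKR
QLIDVSSCTSQQSTMFSKEYGNILGVPTATTHPVVLSRRCCELPGISPLPWNRYAWLRRV
RVLRLIPTLTPGLCFASSHEILTKKPSQLAFSTFIQVTPPATDALYACILIVIPSHRVCL
NIDEAHGKLVKAPQGTLQLVNHMNSTKFIDNYSQGCALPVPQSALSGRTIACMLQRAVTI
DCSELRIGSNRTNLTLAFRSVRSRSTVAIIFSWWPVQLSTSPLNHQGRYVCYRFSIAEFM
LRFSTSRLYAATFFLKPEDGGSGGTLNGVICYCRVKLVLHFSCITQQHLVRSPWDAHARV
KTKAAIYTLERHYTRCGERLYIETEYTPRLGEPPRTVACVSIVAW
>BRAF|canine
MVSIFEASSTGKHGRLEFSSMANNLGNEYGGLLIHQPQHRSRPWPLDGKSTHTRRSAYST
KVTCPAPLMSARASKLSPQPRCESQCRTHNRAHSLYEPGDFTFQVPTLVTVERCMEHLTP
EGSHLPCVSRQVRTLETGKGRAGTGKSPQVHGLGREDRNSRPPVLYKLRADATRMFNGDG
SLPSAFRLYAFYQNNAGNSGGASANSCKKPFALGAFRTVPMFCLWISKLAISATREHQVN
LVVGRSYTLVVYLFVGNHSCLLEQYVPTLVRLMAGFQQRIIMDFHVARYIERAGLTSTKR
QLIDVSSCTSQQSTMFSKEYGNILGVPTATTHPVVLSRRCCELPGISPLPWNRYAWLRRV
RVLRLIPTLTPGLCFASSHEILTKKPSQLAFSTFIQVTPPATDALYACILIVIPSHRVCL
NIDEAHGKLVKAPQGTLQLVNHMNSTKFIDNYSQGCALPVPQSALSGRTIACMLQRAVTI
DCSELRIGSNRTNLTLAFRSVRSRSTVAIIFSWWPVQLSTSPLNHQGRYVCYRFSIAEFM
LRFSTSRLYAATFFLKPEDTLNGVICYCRVKLVLHFSCITQQHLVRSPWDAHARVKTKAA
IYTLERHYTRCGERLYIETEYTPRLGEPPRTVACVSIVAW
>NRAS|human
MAHLPAPGGREFRDVDSAREWSDLELDLISNRGLFVLRMLFVATSIVSNVSANGARLTAG
QYSCRDFQRAANVTRRGFTRRHGGRSLFALSVYYRSTLNRRPESSVESWRTRPPSRFSVL
NVRGILSKRRETVTPTHPQLVMWGLSQEFICWGIPIRADSVTQRLTTMTYGRRIYRRGLV
DSAFEYGNY
>NRAS|canine
MAHLPAPGGREFRDVDSAREWSDLELDLISNRGLFVLRMLFVATSIVSNVSANGARLTAG
QYSCRDFQRAANVTRRGFTRRHGGRSLFALSVYYRSTLNRRPESSVESWRTRPPSRFSVL
NVRGILSKRRETVTPTHPQLVMWGLSQEFICWGIPIRADSVTQRLTTMTYGRRIYRRGLV
DSAFEYGNY
>SMO|human
MSSYETLASTTLSKRCTKTWRLGVVKTPPPRSEHNSGPIIGRFKFAHRLIKTLYTDVTKR
NHETSKSNSERINNVANELLGCFGTYKIFYTRSSWLRLIDSGTSDIRYVPGGNSMIEIAK
GLIHHVALTQSLLVVNSWLPYALVPRHVTTRVRSVRRRFIGGAATGTHCHLLPPGFLFGC
GTRSHCCHRDCMWSRLDVCAPRTQYLQTDLRKVDSPGRGYSLSKQPRCFIKPISAFKNPW
VARAWVRNLLKKAPHSNFHTTRNLVQLGYDGCRHRFINMNTQQVTDTKNYLQSLEPTAGT
IRIPVQHRNSRYLWIRQIRYRSLAIWRAIVGSTPGPHIGMSLQKIGHSLGSMQGICNDNV
VTLATGGTPYPSFTEVTQLYKTISLRLLTAARTDAVLTPPLFGSPVEFSAHLTLKRLHGN
SSRFNCSALSRKVNLRHVLQGKTRTGPCSCIEPRRVDLDISWNSMITDKRIQLKITDCLL
AVRQAKTNSWLESYGHRHTVGGGSLVSLYVEGCTSSLHRIHLSLCEQHRAAVDGWNFIKC
HIRAYAATLCFSTEHRHQNR
>SMO|canine
MSSYETLASTTLSKRCTKTWRLGVVKTPPPRSEHNSGPIIGRFKFAHRLIKTLYTDVTKR
NHETSKSNSERINNVANELLGCFGTYKIFYTRSSWLRLIDSGTSDIRYVPGGNSMIEIAK
GLIHHVALTQSLLVVNSWLPYALVPRHVTTRVRSVRRRFIGGAATGTHCHLLPPGFLFGC
GTRSHCCHRDCMWSRLDVCAPRTQYLQTDLRKVDSPGRGYSLSKQPRCFIKPISAFKNPW
VARAWVRNLLKKAPHSNFHTTRNLVQLGYDGCRHRFINMNTQQVTDTKNYLQSLEPTAGT
IRIPVQHRNSRYLWIRQIRYRSLAIWRAIVGSTPGPHIGMSLQKIGHSLGSMQGICNDNV
VTLATGGTPYPSFTEVTQLYKTISLRLLTAARTDAVLTPPLFGSPVEFSAHLTLKRLHGN
SSRFNCSALSRKVNLRHVLQGKTRTGPCSCIEPRRVDLDISWNSMITDKRIQLKITDCLL
AVRQAKTNSWLESYGHRHTVGGGSLVSLYVEGCTSSLHRIHLSLCEQHRAAVDGWNFIKC
HIRAYAATLCFSTEHRHQNR
>PTEN|human
MFLAFDAHDLAIGPTDEYFTCKKQPILTNSWICLHTFFVIVWLLGENRLHKRHLSGITTA
DRSTKCQPSNTTRCLRSLQEHRRATGACYVDGTVNGILLDHSPPCQQVRATSRASAMILQ
VSLSANPNRRLIAILGWLYMSLAVDINGERERRQENTRCVGGCLILLPARSHLLRREHLI
SMLLTGLPTFRSQCCPLMAL
>PTEN|canine
MFLAFDAHDLAIGPTDEYFTCKKQPILTNSWICLHTFFVIVWLLGENRLHKRHLSGITTA
DRSTKCQPSNTTRCLRSLQEHRRATGACYVDGTVNGILLDHSPPCQQVRATSRASAMILQ
VSLSANPNRRLIAILGWLYMSLAVDINGERERRQENTRCVGGCLILLPARSHLLRREHLI
SMLLTGLPTFRSQCCPLMAL
>SMAD4|human
MLVKIARDIFAILDRVCGANEKTKIVAGTRANNAFELRLPTLSAEADTRLTRLQNIHTKE
AMLLSPVQRALKDLNHVSIKNRPVIHTGQNVPVRPIDLTARGQVLRQALGSGLCSPSREL
GQSIYSRKGPCVLSLKLSRPALAEPYRRTYVAVLRYTVQYKGLASVVSVPPSWLNTAVLS
SYFAPVPKSISRSVGVPSDGLWVVGHFKLATRQGLKPRNCKIPYLKVKVLKRIYPPHEPQ
EVLFIPIDIA
>SMAD4|canine
MLVKIARDIFAILDRVCGANEKTKIVAGTRANNAFELRLPTLSAEADTRLTRLQNIHTKE
AMLLSPVQRALKDLNHVSIKNRPVIHTGQNVPVRPIDLTARGQVLRQALGSGLCSPSREL
GQSIYSRKGPCVLSLKLSRPALAEPYRRTYVAVLRYTVQYKGLASVVSVPPSWLNTAVLS
SYFAPVPKSISRSVGVPSDGLWVVGHFKLATRQGLKPRNCKIPYLKVKVLKRIYPPHEPQ
EVLFIPIDIA
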