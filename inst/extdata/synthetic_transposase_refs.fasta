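>synthref_DD34E
MGKTAVKFLGQTWHKADYAYCLWFCFAGKYKHNQSHYFKTDDEMLSFITRRGDFEDIDLEDVEMAFESSMPHEIHFQECQ
HWADQRNALSARGLQIIEFFQLVMCDGNIRQTFFYAFRWCTAELWQGWHFHQSAQRTPLANVTMTLWVCFMHCYVCKWSQ
AVKMQPLKWLTNFTQFQGGDHFWVPHELDTGRNIRELNVEGCTDDEQSNLRNYYSYIQQMTLMYGEENWKETDMRIRSFR
ASYVGLYTWLCWRCLQGCMKIGLWGDAVQHVMYERQISDNETKTGWKGYAFKEPSFQTNNEGRLTCCSVMGPGQVQICFM
NESWDFMVMWEVNECISATC
>synthref_DD34D
MGKTIECDAADPIGEHGRYERMWSNPDDMSRLRSARHGVDYECWGQFCPHPQDAFHSSQISFERRFADVMFARRHERFGL
HINTNHTKKFVLNACIIWPLKLRTGRYSDVIAPWVHVMYCPFCQYNKKLFMFASAQLWAQFVHVRFRCTQWQPFWCHMIY
CRPQRDRPYLYAMIFNGTIAFPWVPHELDTGRNVYAYHTHHDSKVGVCMGIMLLQGKPGHQDPTHNAACHDPFGHIAMMQ
QPHQLDQIAEGEFGCGTIHKIGLWGDAVQHIFNWHLKNMLFCRGVPPGVKQNISSFQTNNDGRLTFPGGQRDQMQNYFQY
EDSDWSCTHCNGARWHKIHI
>synthref_DD35E
MGKTPGTWWNDYSVRCTHVMQWKEIAQHNDTANQAMWKHAQPDSWQKQTWGFYPHYGQMNQDSDFRKRCHSVQYVMVMQE
ICWWGYFQFAEHNCEYDEVIYVIVNKQDNHVVEYYEEPTHYINCTWTAQLYFISQIMVTRQMYWLVICVKIPQGMKFHAE
KYNEFSIYRAKHLENSFKRKRWVPHELDTGRNTRNLGHMKSTKFIRNNNHNYFFCKVCMFWICLVPYDEDGVRVQIRIDH
QQLFLPKLVFSCMAPPGYKIGLWGDAVQHCGTWFMNMHVDHMLCPKFPWSSDWWSFQTNNEGRLTCLFDWTFYMGRSTHC
EPIHHSRTWTTPVVEKNCIV
>synthref_DD37D
MGKTFFTYNMYITSRDWDMKCHVSRTWMGKFSKDNGPGMMGWFWMTEYTLSFGMANGCIGTQNIQCTDLYPPIMTEKATY
QEFDACECTKNNMCMDHQIPIMSIKLRLPNCEYPQMLFMEQDKAVKRSITNITLYVCFHLCDCRPEPFGIHMMNIRHMTQ
YVCRRWAFDNLNQLWPDCSWVPHELDTGRNCERAQWIFRTACWAKEAPHSETNLNKRIRKWWWLIEVSQVPRTCCIMEGD
MNDNWWNMKKINLELIKIGLWGDAVQHEFWSMTYVIQKMRRDGTAWLIMRRAQMSFQTNNDGRLTHSTYLLWRFMGAHFM
EQGWLYSCQGYPGPCCMGKH
>synthref_DD37E
MGKTWHDDRRMIFEQFLQDNKHNHTVKRCSDIPDCIGFGHLVIRMSQKMCGMNADDHHNFQETAGDNVLHCQCFIVPIFF
LWFEIEPLAHHGGDCYTWGDLGERSNSWAVFQDNAVYHETRWQINCNHSGHIAFVIEAVIRCIWPGKCLWNEIQYVLSNS
CDDDGCDWSMWVQCNDLMWWVPHELDTGRNEYKMGDMVYERDKLANNPWGYQILEPPMEEVMCKYTDLWCQFRMWVFNDQ
TYFAFGLCLADYHMQPKIGLWGDAVQHKDEKHHCMHHDDHTQCSGMDWIACTQRSFQTNNEGRLTKNGDYAYWPGIPFPV
RFRFTWAWPMCEWQRFPHGE
>synthref_DD39D
MGKTPKRLKQDVMDENNFDHHFENVTIQSHLDDNHPMSHCERFSITCVEMAFNAQFHDAHKIMDVNNQALRQAYKQMAKL
ANVDMYFPASNSVNPVMEVYNHCNIYDVIQILMIIMIHEEFANSSMCIRCFLCTWGQDPYWSFAFWRHTPQFICTSDHPT
MCDVAPQLIAWCPLQRQWVPHELDTGRNNDQCFAMNHLDYVEKKHMKFPQGDKQCNIRLQVFEYYNQQCDNQEDSQELGG
LTILYDTPDQKTLKKIGLWGDAVQHFWLPIDQATKNEVAGYSLNWTQYWITAMQSFQTNNDGRLTWYRADDCNSYYNNRV
SGRDECQILQKHCCMCDLVF
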