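>CYP450_CANAL synthetic stand-in sequence
HWNFSDWAEYMPEQMWAGHKVAIWMIMNSFAYVLQMTYSCQYTKMHYWAKTDHCCMMDTY
MINLWHAGNHILWDHGPLNVIDKWIFCDTPCTHQDSASHYETWFPCSYNVRIDNANLPFM
IRKFCRPNGTWTSIYAGRIFHNWFKGCIIF
>CYP450_HUMAN synthetic stand-in sequence
HWEWWWWHCRPVEQCTYHHKVSINMVMFSFFYVQQMEYMAHYWKMTYWAKTDHMFMMDTC
LCILWHAMNHHLWRKASSYYGYWWHGCVIPCKVQDSWSDPHANFPLFYNVRLTHSNLHTM
IFIFWRPNGMWTWFCADRVSNNWFNNSEIQ
>ODC_TRYBR synthetic stand-in sequence
METSKASPMPCWLCGYFGEIEYQAEYPSEVCIPHMIPWFLEAKGRGYQHWEALYRSTFCG
QAFYACPNEGMPGFLAKYKQINKWGIGIAINLSEIWGFGFHCQDCFHFCYLKVSGMQGGP
RPPAHVIFDHALGRTSMTECGRDHNPILTV
>ODC_PNECA synthetic stand-in sequence
MWTTKQKSMPCWILTYFQENCYTAEYPYRGCIWHMIWWKPLATCRGSQCWYGDPRQTFMG
LMVYWGVEHGQPGKAAWIAKQGKWGIGRTINDGENHFDEQFMKQQVHFCYLKVNFMQGGP
CPPRQVSFDHAAGRRSGEPCGRMHAPIKAR
>DHPS_MYCLE synthetic stand-in sequence
RVMYYWGHVSPLFQIAYHADVTDGMTCRLEVYKMRHFTAEPKDEWVDKCRQYDLGVGRRK
NCMPYFSRWQLQSSLLASLVTTYQINDEHGCKCHSCLPMFRWRAIKRQALNAPWCFIELT
YHSHFINYVEFWKGACWLWWCLVNGRVHPF
>DHPS_TOXGO synthetic stand-in sequence
CDIQYKGWVEPDWFIADHSDYTDWMGCRLEHYKMRHFTTEKPMEIMDKCRQYDLWVGWAK
NCMTKFVRNQNQKSLLAVSHTSCQVNDEAGCKCTSCNQMGRHRAESLVLFFAPWCFIEPT
YKSHFINYVEFWKMWCYYWGCRVNGRVFPD
>CYTB_PNECA synthetic stand-in sequence
LWNPHDGFMDPINCGHEYRHCKTRWFKLEWERDAHINGSFPQAYKNFIMHGFPNYWTIRA
MEEICQVHPCRLHQAFIMWLGTLDMKPCYIAHQIVKGWCLFWPCNSCGQSLTSMRTKPPQ
MRKLQSMFILQHLIPRRKRKAHAFMQHNYH
>CYTB_TOXGO synthetic stand-in sequence
QVNNLKVFMAPINAMHFYRHCNGWWWYLEWGSDARKRWSFPQARRNFFMHGFWMYWIIRC
DEEVCQAHPCRLHQDLECWLGTTDLKKCIINHQWVYRWCLFYPHDYPCQNLTSMKTKPLQ
MRKVQSMFHLGHHYPKRKRKAHAVMVRAML
>DHFR_PNECA synthetic stand-in sequence
AWPVTYPGNFPTEFHGNAAYYLKCDQFMRNKNPQYWNVAHNGWCFSRPTHQHWIFHIWVI
LGEGPHCYAVQIACTGCGWHFMWGCTSQMIYTMFQCQLVYHQSELMMFEEGNWESNKWNR
VTCCASQIIGYVVDTYACTNTQIIWLMFVI
>DHFR_HUMAN synthetic stand-in sequence
ATPVTYKGNEHMEFHGNAAYVLKCFQFGRNKNPLYSNEGHQPPCFSPPEHQHWILHMWVI
CVEGPHCYCVFPNCTGWGWMFWDGCTSQAIYVMFQCDLCYQQSALPMTVEGNWYSNKHND
VSCIASQFIPYFVLGMSSTGTQVIKLGFVR
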