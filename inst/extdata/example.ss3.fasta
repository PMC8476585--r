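>rossmann_f1_s001|fam3|rossmann
EEEEEEECCCCCHHHHHHHHCCCHHEEECCEHHCCEEEEEEEECCHHHHHHHCCCCCCCE
EEC
>rossmann_f1_s002|fam3|rossmann
EEEECCCCCHHHHHHHCCHHEEECEHHHCCEEEEHECCCCCHHHHHHHHHHCECCCCCEC
>rossmann_f1_s003|fam3|rossmann
EEEEEECCCCCHHHCCHHHHHCCCEHEEECCHHHCCEEEEHECCCCHHHHCHHHHCEEHC
CC
>dual-rossmann_f1_s001|fam1|dual-rossmann
EEEEECECCHHHHHHHHHHHHCCCCEEEECCCCHHHHHCCCCCEEEEEECCCCCCCCCCC
CCCCCCCCCCCCCEEEECEEECCCCCCHHHHHHHHHHHHHCCCEEHCCCCCHHHHHHHHH
HHHCCCEEEEECCCCCHCC
>dual-rossmann_f1_s002|fam1|dual-rossmann
EEEEEECCHHHHHHHHHHCCCEEEEECCCHHHHHHHHHCCHCECECCCEEEEECCCCHCC
CCCCCCCCCEEEEEEEEECCCCCHHHHHHHHCCHHHCCCEEEECCCCCHHHEHHHHHHHC
CCCCECEEEEECCCCCCCCC
>dual-rossmann_f1_s003|fam1|dual-rossmann
ECEEECCHHHHHHHHHHHCCCECEEEECHHHHHCCCCCCCEEEEEEECCCCCCCCHCCCC
CCCCCCECCCEEEEEECHCHHHHHHHHCHCCCEEEEECCCHHHEHHHHHHHHHHCCCCCC
EHEECCECC
>membrane_f1_s001|fam2|membrane
HHHHHHHHHHHHHHHHHHHCCHHHHHHHHHHHHHHHHHHCCCCCECCCCCCCCCCCCHHH
HHHHHHHHHHHHHHHCCCHEHHHHHHHHHHHHHCCHCCCCEEEEEEEHEHHHHHHHHHHH
HHHHCH
>membrane_f1_s002|fam2|membrane
HHHCHHHHHHHHHHHHHHHHHCHHHHHHHHEHHHHHHHCHHCHHHHHHHHHHHHHHCHHH
HHHHHCCHHHHHHHHHHHHCHCCCCCCCCCEEEEEEEHEEEHHHHHHHHEHHHH
>membrane_f1_s003|fam2|membrane
HHHHHHHHHHCHHHHHHCHHHHHHHHHHHHHHHHHCCCCCCCCCCCCCCCCCHHHHHHHH
HHHHHHHHHHHHCCCCCCCCCCHHHHHHHHHHCHHHHCHHCCCCCCCCCEEEEEEEHEEH
HHHHHHHHHHHHHHH
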