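>alf_synthetic_ref synthetic ALF-like reference (mature)
QWYKLVVGLVAGALLTVFAAPSIIGEAVCKTRGWEAHKSYSGRLGNPRVRRSGCPGYTLRPGIKATVSEY
VRSGVDVNRAWQSHASNGLVSRSDAATWLSKFA
>crustin_synthetic_ref synthetic crustin-like reference (mature)
QTYHPPRVPSMVRPHAQYVAPNEWKSTFNAPSVSRPGYLPCPNVRGQCLMSCSSDESCPGGYKCCSNGGC
GHVCMAPCFKEPCGRTCSQVC
>armadillidin_AvulgareH_ref A. vulgare armadillidin H mature
GHLGRPYIGGGGGFNRGGGFHRGGGFHRGGGFHSGGGFHRGGGFHSGGSFGYR
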