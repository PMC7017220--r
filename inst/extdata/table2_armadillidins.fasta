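>A_assimile
GHIRRPYIGGGGLYGGGGGFHRGGGFHRGGGGFIGGGGFHRGGGFNRGGSYGYNG
>A_depressum
GGFGRPYIGGGGFNRGGGLHRGGGFNSGGGFNRGGGFNRGGGFNRGGGFHRGGSFGYNG
>A_maculatum
GGFGRPYIGGGGFNRGGGFHRGGGFRSGGGFHRGGGFNRGGGFHRGGSYGYNG
>A_nasatum
GHIGRPYIGGGGGGIYRGGGFRTGGGFRTGGGFHRGGGGFHRGGGFHRGGSYGYNG
>A_tunisiense
GHIGRPYIGGGGIYRGGGFRTGGGFHRGGGFHRGGGFQRGGGFYGGGSYGYNG
>A_versicolor
GGFGRPYIGGGGFNRGGGFHRGGGFNRGGGFHRGGGFNRGGGFHRGGSFGYNG
>A_vulgare_H
GHLGRPYIGGGGGFNRGGGFHRGGGFHRGGGFHSGGGFHRGGGFHSGGSFGYR
>A_vulgare_Q
GHLGRPYIGGGGGFNRGGGFHRGGGFHRGGGFQSGGGFHRGGGFHSGGSFGYR
>A_officinalis
TFKPCGRSSGGSRCNRGYNRGIIGISGGNNKINGGGDFDDDDYESDYEDYNNGIIGIRGGTNTVNGGGSN
NPKDSALKDYNNGIIGIGGGTNTVNGGGSNNPKDSAFKDPRGNRGIIGISGGRNVVQRG
>C_elongata
TPGRPYYGGGYNGGYRGGYRRGGGFYGGGRFYGGGEGYRGGYYRGYRG
>E_purpurascens
SYVRRPYIGGGGGGFHRGGGFHRGGGFISGGGFHRGGGFNRGGGYGYNG
>P_dilatatus
GHHGYGGSYGGRRYGHGGGRFGGIRGGGYGGGGHIGGGYGGYGGYRG
>P_dispar
GYIRKPYIGRGYGGGGYHRGGGFGYGGGYYRGGVGYGGGGYGGYGYRG
>P_laevis
SFIRKPYIGGGYGGYRGGGGYGGYRGGYYRGGGHYGGGYGGYGYRG
>P_muscorum
TFGRPYYGGGFNRGFGGGYHRGGGFHRGGGFYGGGFRGGYNRGYLG
>P_pruinosus
SYGRGSYGGGSIGRGSFGHGGGSFGRGGGRFGHGGGRFGGIGGGGRYGGGHIGGYRG
>P_scaber
GYIRRPVGYYGGGGGRYGGGRFGGGGGGIGGGRYGGGGRYGGGSYGGYHG
>O_asellus
TYRPSYGGGGGFNRGGGRGGGIHRGGGIGGGIYRGGGIGGGHRGGGGGRFNRGYGYR
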