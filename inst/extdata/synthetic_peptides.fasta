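>armadillidin_CE synthetic peptide, C. elongata mature
TPGRPYYGGGYNGGYRGGYRRGGGFYGGGRFYGGGEGYRGGYYRGYRG
>armadillidin_PP synthetic peptide, P. pruinosus mature
SYGRGSYGGGSIGRGSFGHGGGSFGRGGGRFGHGGGRFGGIGGGGRYGGGHIGGYRG
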