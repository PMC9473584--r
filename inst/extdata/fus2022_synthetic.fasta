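>fus2022_synthetic composition-matched synthetic sequence (526 aa, 34 Tyr, 34 Arg); not the natural FUS sequence
PPQGYPEQQYYDNSEGYMYNANTTYQQEENNYPMATRPMDSMETPNTSDYEGDSDSRSPM
GAMQGASATMEDNASATENNAYGTAPQTNNYMNPDAQEMETARDGMYSPPATEQATMNQN
DRGGNATTPYSDGPGAMARATGREAPMTAGDSSYDEYPYGGMETTARESYNTGMGDPEER
EMMAQEEQYMTGYQGSPDSNNSNSGTAYRADEGDESQPRTPMDRQPENGYDYQRNNNRST
PGEMTEDRMQPMTPMEATNENTESNRTRGTPSEDEMANTNNRGQSRRGMMNQSSDSNDAD
PEYADGTDATRNQDRSTAGPSMMATEQYTEDDPQYTQDTAEGNDSYSNESTRSANESNMQ
MRDMENAPPSANMSRQPPQTTSPSGSTQTGQNTQADQPPYRQRMQDSSQEPTQDPDAMAM
YAMAEQDRGQMAMATSRNGTRYTMTNDPPGAYMYSAPTDEDAGDTPDEGREDGPSGMPPY
DAAENSARRSADMTDGGRTGEYYNAANDMAYGTPGNEPGMSDRQEQ
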