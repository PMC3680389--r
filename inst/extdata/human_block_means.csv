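treatment,block,mean_contribution,provenance
message,1-10,8.33,"reported mean contribution, human experiment, message treatment, rounds 1-10"
punishment,1-10,6.25,"reported mean contribution, human experiment, punishment treatment, rounds 1-10"
sanction,1-10,8.23,"reported mean contribution, human experiment, sanction treatment, rounds 1-10"
message,16-20,9.90,"reported mean contribution, human experiment, message treatment, rounds 16-20"
punishment,16-20,10.65,"reported mean contribution, human experiment, punishment treatment, rounds 16-20"
sanction,16-20,14.46,"reported mean contribution, human experiment, sanction treatment, rounds 16-20"
message,21-30,5.05,"reported mean contribution, human experiment, message treatment, rounds 21-30"
punishment,21-30,3.75,"reported mean contribution, human experiment, punishment treatment, rounds 21-30"
sanction,21-30,9.08,"reported mean contribution, human experiment, sanction treatment, rounds 21-30"
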