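level,score,count
student,1,8
student,2,4
student,3,0
student,4,0
resident,1,1
resident,2,12
resident,3,17
resident,4,11
fellow,1,0
fellow,2,0
fellow,3,4
fellow,4,6
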