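subject,gender,age_yr,height_cm,weight_kg
subject 1,Male,35,174,62
subject 2,Male,25,175,80
subject 3,Male,26,167,56
subject 4,Male,28,185,84
subject 5,Male,58,172,64
subject 6,Male,37,170,70
subject 7,Male,49,165,85
subject 8,Male,28,181,100
subject 9,Male,31,170,80
subject 10,Male,59,172,67
subject 11,Female,29,163,58
subject 12,Female,47,167,58
subject 13,Female,56,158,63
subject 14,Female,36,153,47
subject 15,Female,23,163,55
subject 16,Female,22,160,48
subject 17,Female,21,159,54
subject 18,Female,21,165,48
subject 19,Female,24,163,68
subject 20,Female,22,161,52
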