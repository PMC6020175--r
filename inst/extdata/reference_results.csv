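condition,tp,fp,fn,precision,recall
Character substitution (3%),8191,538,391,93.9,95.5
Character substitution (10%),7740,447,826,94.6,90.4
Character substitution (20%),6969,271,1537,96.3,82.0
Address alias substitution,8171,486,455,94.4,94.8
Address token removal,2761,99,237,96.6,92.1
"OCR (3% char. sub., 3% white space)",8464,160,1555,98.2,84.5
"OCR (10% char. sub., 10% white space)",5327,180,7282,96.8,42.3
"OCR (20% char. sub., 20% white space)",1802,151,14719,92.3,11.0
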