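reminder_id,label,a,b,c,d
1,Overdue for A1c,85,20,7,293
2,Almost due for A1c,11,1,2,391
3,Recent A1c was over 8,4,4,15,382
4,Due for microalbumin screening,110,15,32,248
5,"Renal disease, consider ACE inhibitor",12,34,44,315
6,"Renal disease, contraindications for ACE inhibitor, consider ARB",1,0,3,401
7,Due for eye exam,204,12,8,181
8,Due for foot exam,140,27,7,231
9,Due for blood pressure,84,127,9,185
10,"CAD, consider anti-platelet",35,8,72,290
11,"CAD, consider anti-platelet, but contraindications exist",2,29,2,372
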