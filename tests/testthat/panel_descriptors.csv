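smiles,mw,clogp,tpsa,hba,hbd,n_rot
CC,30.07,1.0262,0.0,0,0,0
CCC,44.097,1.4163,0.0,0,0,0
CCCC,58.124,1.8064,0.0,0,0,1
CCO,46.069,-0.0014,20.23,1,1,0
CCCO,60.096,0.3887,20.23,1,1,1
COC,46.069,0.2626,9.23,1,0,0
CCOC,60.096,0.6527,9.23,1,0,1
CCCC(=O)O,88.106,0.8711,37.3,2,1,2
CCCOC,74.123,1.0428,9.23,1,0,2
CC(C)C,58.124,1.6623,0.0,0,0,0
c1ccccc1,78.114,1.6866,0.0,0,0,0
Cc1ccccc1,92.141,1.995,0.0,0,0,0
CCc1ccccc1,106.168,2.249,0.0,0,0,1
Oc1ccccc1,94.113,1.3922,20.23,1,1,0
COc1ccccc1,108.14,1.6952,9.23,1,0,1
c1ccc(cc1)C(=O)O,122.123,1.3848,37.3,2,1,1
CC(=O)O,60.052,0.0909,37.3,2,1,0
CCC(=O)O,74.079,0.481,37.3,2,1,1
CC(=O)OC,74.079,0.1793,26.3,2,0,0
CCC(=O)OCC,102.133,0.9595,26.3,2,0,2
CC(C)O,60.096,0.3871,20.23,1,1,0
OCCO,62.068,-1.029,40.46,2,2,1
OCCCO,76.095,-0.6389,40.46,2,2,2
COCCOC,90.122,0.2792,18.46,2,0,3
CC(=O)OCC,88.106,0.5694,26.3,2,0,1
OCCOCCO,106.121,-1.0124,49.69,3,2,4
Cc1cccc(C)c1,106.168,2.3034,0.0,0,0,0
CCCCCC,86.178,2.5866,0.0,0,0,3
CCCCCCCC,114.232,3.3668,0.0,0,0,5
CCCCCCCCCC,142.286,4.147,0.0,0,0,7
CC(C)Cc1ccccc1,134.222,2.8851,0.0,0,0,2
OCCc1ccccc1,122.167,1.2214,20.23,1,1,2
CCOc1ccccc1,122.167,2.0853,9.23,1,0,2
c1ccc2ccccc2c1,128.174,2.8398,0.0,0,0,0
Cc1ccc(C)cc1,106.168,2.3034,0.0,0,0,0
CC(=O)Oc1ccccc1C(=O)O,180.159,1.3101,63.6,4,1,2
CC(C)Cc1ccc(cc1)C(C)C(=O)O,206.285,3.0732,37.3,2,1,4
Oc1ccccc1O,110.112,1.0978,40.46,2,2,0
COCCOCCO,120.148,-0.3583,38.69,3,1,5
CCCCO,74.123,0.7788,20.23,1,1,2
CC(C)(C)O,74.123,0.7772,20.23,1,1,0
CCCc1ccccc1,120.195,2.6391,0.0,0,0,2
C1CCCCC1,84.162,2.3406,0.0,0,0,0
C1CCCC1,70.135,1.9505,0.0,0,0,0
CC1CCCCC1,98.189,2.5866,0.0,0,0,0
OC1CCCCC1,100.161,1.3114,20.23,1,1,0
CCC(C)O,74.123,0.7772,20.23,1,1,1
CCOCC,74.123,1.0428,9.23,1,0,2
CCCCCO,88.15,1.1689,20.23,1,1,3
OCC(O)CO,92.094,-1.6681,60.69,3,3,2
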