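v_feed125: unlabeled
v125,out: X125
v125,38: X125
v_prod38: unlabeled
v38,25: X38
v25,24: X25
v25,26: X25
v25,out: X25
v24,12: X24
v_el: X12
v23,out: X23
v_ser_in: unlabeled
v13,out: X13
v12,1: X12
v1,2: X1
v2,5: X2
v2,3: X2
v2,4: X2
v4,out: X4
v5,7: X5
v5,6: X5
v6,out: X6
v3,7: X3
v3,8: X3
v7,8: X7
v7,out: X7
v8,18: X8
v8,20: X8
v18,19: X18
v18,21: X18
v19,22: X19
v20,out: X20
v20,dil: X20
v21,out: X21
v21,dil: X21
v22,out: X22
v22,dil: X22
v12,11: X12
v11,9: X11
v11,14: X11
v14,out: X14
v9,10: X9
v9,15: X9
v10,out: X10
v15,out: X15
v_ino_in: unlabeled
v16,out: X16
v_eth_in: unlabeled
v17,out: X17
v26,27: X26
v27,28: X27
v28,29: X28
v28,out: X28
v29,30: X29
v30,31: X30
v31,32: X31
v30,33: X30
v33,30: X33
v33,dil: X33
v31,34: X31
v34,31: X34
v34,dil: X34
v32,35: X32
v35,32: X35
v35,40: X35
v40,35: X40
v35,dil: X35
v40,39: X40
v40,dil: X40
v32,37: X32
v37,32: X37
v32,39: X32
v39,32: X39
v36,37: X36
v37,36: X37
v39,36: X39
v36,39: X36
v32,186: X32
v32,dil: X32
v36,dil: X36
v37,dil: X37
v39,dil: X39
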