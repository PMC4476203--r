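id,name,side,district,length_cm,diameter_cm,upstream_node,downstream_node
OV_l,OV_l,left,intracranial,4,0.21,brain,cav_l
OV_r,OV_r,right,intracranial,4,0.21,brain,cav_r
ICV_l,ICV_l,left,intracranial,3.5,0.126,brain,galen_conf
ICV_r,ICV_r,right,intracranial,3.5,0.126,brain,galen_conf
RV_l,RV_l,left,intracranial,4,0.126,brain,galen_conf
RV_r,RV_r,right,intracranial,4,0.126,brain,galen_conf
ISS,ISS,midline,intracranial,5,0.126,brain,srs_orig
GV,GV,midline,intracranial,1.5,0.245,galen_conf,srs_orig
SRS,SRS,midline,intracranial,5,0.315,srs_orig,torcular
SSS,SSS,midline,intracranial,24,0.455,brain,torcular
TS_l,TS_l,left,intracranial,7,0.385,torcular,sigj_l
TS_r,TS_r,right,intracranial,7,0.385,torcular,sigj_r
SS_l,SS_l,left,intracranial,5,0.42,sigj_l,jug_l
SS_r,SS_r,right,intracranial,5,0.42,sigj_r,jug_r
CS_l,CS_l,left,intracranial,2,0.28,cav_l,pj_l
CS_r,CS_r,right,intracranial,2,0.28,cav_r,pj_r
SPS_l,SPS_l,left,intracranial,4,0.21,pj_l,sigj_l
SPS_r,SPS_r,right,intracranial,4,0.21,pj_r,sigj_r
IPS_l,IPS_l,left,intracranial,3.5,0.245,pj_l,jug_l
IPS_r,IPS_r,right,intracranial,3.5,0.245,pj_r,jug_r
BP_l,BP_l,left,intracranial,2.5,0.12,cav_l,bp_conf
BP_r,BP_r,right,intracranial,2.5,0.12,cav_r,bp_conf
POS,POS,midline,intracranial,3,0.15,torcular,pos_conf
POS_l,POS_l,left,intracranial,2.5,0.12,pos_conf,occ_conf
POS_r,POS_r,right,intracranial,2.5,0.12,pos_conf,occ_conf
CP_a,CP_a,midline,cervical,3,0.25,bp_conf,c0
CP_p,CP_p,midline,cervical,3,0.22,occ_conf,c0
IJV_l,IJV_l,left,cervical,15,1.2,jug_l,scv
IJV_r,IJV_r,right,cervical,15,1.2,jug_r,scv
CP1,CP1,midline,cervical,2.5,0.8,c0,c1
CP2,CP2,midline,cervical,2.5,0.8,c1,c2
CP3,CP3,midline,cervical,2.5,0.8,c2,c3
CP4,CP4,midline,cervical,2.5,0.8,c3,c4
CP5,CP5,midline,cervical,2.5,0.8,c4,c5
CP6,CP6,midline,cervical,2.5,0.8,c5,c6
CP7,CP7,midline,cervical,2.5,0.8,c6,c7
VV_l1,VV_l1,left,cervical,2.5,0.55,vl1,vl2
VV_l2,VV_l2,left,cervical,2.5,0.55,vl2,vl3
VV_l3,VV_l3,left,cervical,2.5,0.55,vl3,vl4
VV_l4,VV_l4,left,cervical,2.5,0.55,vl4,vl5
VV_l5,VV_l5,left,cervical,2.5,0.55,vl5,vl6
VV_l6,VV_l6,left,cervical,2.5,0.55,vl6,scv
VV_r1,VV_r1,right,cervical,2.5,0.55,vr1,vr2
VV_r2,VV_r2,right,cervical,2.5,0.55,vr2,vr3
VV_r3,VV_r3,right,cervical,2.5,0.55,vr3,vr4
VV_r4,VV_r4,right,cervical,2.5,0.55,vr4,vr5
VV_r5,VV_r5,right,cervical,2.5,0.55,vr5,vr6
VV_r6,VV_r6,right,cervical,2.5,0.55,vr6,scv
CPVV_l1,CPVV_l1,left,connective,1.5,0.5,c2,vl1
CPVV_l2,CPVV_l2,left,connective,1.5,0.5,c3,vl2
CPVV_l3,CPVV_l3,left,connective,1.5,0.5,c4,vl3
CPVV_l4,CPVV_l4,left,connective,1.5,0.5,c5,vl4
CPVV_l5,CPVV_l5,left,connective,1.5,0.5,c6,vl5
CPVV_l6,CPVV_l6,left,connective,1.5,0.5,c7,vl6
CPVV_r1,CPVV_r1,right,connective,1.5,0.5,c2,vr1
CPVV_r2,CPVV_r2,right,connective,1.5,0.5,c3,vr2
CPVV_r3,CPVV_r3,right,connective,1.5,0.5,c4,vr3
CPVV_r4,CPVV_r4,right,connective,1.5,0.5,c5,vr4
CPVV_r5,CPVV_r5,right,connective,1.5,0.5,c6,vr5
CPVV_r6,CPVV_r6,right,connective,1.5,0.5,c7,vr6
IV_c1,IV_c1,midline,connective,1.5,0.3,qc1,c1
IV_c2,IV_c2,midline,connective,1.5,0.3,qc2,c2
IV_c3,IV_c3,midline,connective,1.5,0.3,qc3,c3
IV_c4,IV_c4,midline,connective,1.5,0.3,qc4,c4
IV_c5,IV_c5,midline,connective,1.5,0.3,qc5,c5
IV_c6,IV_c6,midline,connective,1.5,0.3,qc6,c6
IV_c7,IV_c7,midline,connective,1.5,0.3,qc7,c7
AZ1,AZ1,midline,thoracic,2.2,0.85,az1,ra
AZ2,AZ2,midline,thoracic,2.2,0.85,az2,az1
AZ3,AZ3,midline,thoracic,2.2,0.85,az3,az2
AZ4,AZ4,midline,thoracic,2.2,0.85,az4,az3
AZ5,AZ5,midline,thoracic,2.2,0.75,az5,az4
AZ6,AZ6,midline,thoracic,2.2,0.75,az6,az5
AZ7,AZ7,midline,thoracic,2.2,0.75,az7,az6
AZ8,AZ8,midline,thoracic,2.2,0.75,az8,az7
AZ9,AZ9,midline,thoracic,2.2,0.65,az9,az8
AZ10,AZ10,midline,thoracic,2.2,0.65,az10,az9
AZ11,AZ11,midline,thoracic,2.2,0.65,az11,az10
AZ12,AZ12,midline,thoracic,2.2,0.65,az12,az11
TP1,TP1,midline,thoracic,2.8,0.6,t2,t1
TP2,TP2,midline,thoracic,2.8,0.6,t3,t2
TP3,TP3,midline,thoracic,2.8,0.6,t4,t3
TP4,TP4,midline,thoracic,2.8,0.6,t5,t4
TP5,TP5,midline,thoracic,2.8,0.6,t6,t5
TP6,TP6,midline,thoracic,2.8,0.6,t7,t6
TP7,TP7,midline,thoracic,2.8,0.6,t8,t7
TP8,TP8,midline,thoracic,2.8,0.6,t9,t8
TP9,TP9,midline,thoracic,2.8,0.6,t10,t9
TP10,TP10,midline,thoracic,2.8,0.6,t11,t10
TP11,TP11,midline,thoracic,2.8,0.6,t12,t11
TP12,TP12,midline,thoracic,2.8,0.6,t12,tlj
TPAZ1,TPAZ1,midline,connective,2,0.5,t1,az1
TPAZ2,TPAZ2,midline,connective,2,0.5,t2,az2
TPAZ3,TPAZ3,midline,connective,2,0.5,t3,az3
TPAZ4,TPAZ4,midline,connective,2,0.5,t4,az4
TPAZ5,TPAZ5,midline,connective,2,0.5,t5,az5
TPAZ6,TPAZ6,midline,connective,2,0.5,t6,az6
TPAZ7,TPAZ7,midline,connective,2,0.5,t7,az7
TPAZ8,TPAZ8,midline,connective,2,0.5,t8,az8
TPAZ9,TPAZ9,midline,connective,2,0.5,t9,az9
TPAZ10,TPAZ10,midline,connective,2,0.5,t10,az10
TPAZ11,TPAZ11,midline,connective,2,0.5,t11,az11
TPAZ12,TPAZ12,midline,connective,2,0.5,t12,az12
IV_t1,IV_t1,midline,connective,1.5,0.3,qt1,t1
IV_t2,IV_t2,midline,connective,1.5,0.3,qt2,t2
IV_t3,IV_t3,midline,connective,1.5,0.3,qt3,t3
IV_t4,IV_t4,midline,connective,1.5,0.3,qt4,t4
IV_t5,IV_t5,midline,connective,1.5,0.3,qt5,t5
IV_t6,IV_t6,midline,connective,1.5,0.3,qt6,t6
IV_t7,IV_t7,midline,connective,1.5,0.3,qt7,t7
IV_t8,IV_t8,midline,connective,1.5,0.3,qt8,t8
IV_t9,IV_t9,midline,connective,1.5,0.3,qt9,t9
IV_t10,IV_t10,midline,connective,1.5,0.3,qt10,t10
IV_t11,IV_t11,midline,connective,1.5,0.3,qt11,t11
IV_t12,IV_t12,midline,connective,1.5,0.3,qt12,t12
LP1,LP1,midline,lumbar,4,0.6,tlj,l1
LP2,LP2,midline,lumbar,4,0.6,l1,l2
LPLV1,LPLV1,midline,connective,2,0.4,l1,w1
LPLV2,LPLV2,midline,connective,2,0.4,l2,w2
LV1,LV1,midline,lumbar,4,0.5,w1,w2
LV2,LV2,midline,lumbar,4,0.5,w2,k1
CV2,CV2,midline,lumbar,8,1.5,fem,k1
CV1,CV1,midline,lumbar,6,1.8,k1,k2
CV,CV,midline,lumbar,6,2,k2,ra
IV_l1,IV_l1,midline,connective,1.5,0.3,ql1,l1
IV_l2,IV_l2,midline,connective,1.5,0.3,ql2,l2
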