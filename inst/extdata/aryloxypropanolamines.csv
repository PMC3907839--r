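compound_id,ic50_uM,dg_exp_kJ_mol,molar_mass_g_mol,net_charge_e,role
lig01,18,-31.73,210.30,1,train
lig02,28,-30.59,224.32,1,train
lig03,1.9,-37.53,260.36,1,train
lig04,21,-31.34,266.36,1,train
lig05,100,-27.31,317.41,1,train
lig06,0.03,-48.22,389.52,1,train
lig07,0.05,-46.90,382.46,1,train
lig08,0.28,-42.56,404.60,1,train
lig09,0.35,-41.89,417.55,1,train
lig10,12,-32.78,435.52,0,test
lig11,0.42,-41.42,394.50,1,test
lig12,8.4,-33.70,290.38,1,test
lig13,0.31,-42.20,380.47,1,test
lig14,0.03,-48.22,339.46,1,test
lig15,3.80,-35.74,273.38,1,test
lig16,24,-30.99,268.38,1,test
lig17,2.10,-37.27,464.59,1,test
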