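region,province,effch,techch,sech,pech,tfpch,rank
eastern,Beijing,1.016,0.986,1.014,1.002,1.002,1
eastern,Tianjin,1,0.968,1,1,0.968,15
eastern,Hebei,0.99,0.956,0.99,1,0.946,27
eastern,Liaoning,1.006,0.969,1.008,0.999,0.975,11
eastern,Shanghai,1,0.977,1,1,0.977,8
eastern,Jiangsu,0.997,0.979,0.996,1.001,0.976,9
eastern,Zhejiang,1,0.974,1,1,0.974,13
eastern,Fujian,1.002,0.973,1.002,1,0.975,11
eastern,Shandong,0.998,0.958,0.989,1.009,0.956,23
eastern,Guangdong,1,0.968,1,1,0.967,16
eastern,Hainan,1.003,0.94,0.992,1.011,0.943,28
central,Shanxi,1.025,0.938,1.025,1,0.961,22
central,Jilin,1.012,0.973,1.012,0.999,0.984,4
central,Heilongjiang,1.037,0.958,1.038,0.999,0.993,3
central,Anhui,1.005,0.977,1.003,1.002,0.981,6
central,Jiangxi,1,0.962,1,1,0.962,21
central,Henan,1,0.939,1,1,0.939,29
central,Hubei,1.008,0.964,1,1.008,0.971,14
central,Hunan,1.003,0.949,1,1.003,0.952,25
western,Guangxi,1,0.947,1,1,0.947,26
western,Inner Mongolia,1.006,0.97,1.006,1,0.976,9
western,Chongqing,1.001,0.977,1,1.001,0.978,7
western,Sichuan,1.003,0.964,1,1.003,0.967,16
western,Guizhou,1,0.937,1,1,0.937,30
western,Yunnan,1,0.964,1,1,0.964,20
western,Tibet,1,0.888,1,1,0.888,31
western,Shaanxi,1.007,0.988,1.008,0.999,0.995,2
western,Gansu,1.017,0.951,1.012,1.005,0.967,16
western,Qinghai,1.02,0.938,1.005,1.015,0.956,23
western,Ningxia,1.014,0.953,1,1.014,0.967,16
western,Xinjiang,1.014,0.969,1.011,1.003,0.983,5
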