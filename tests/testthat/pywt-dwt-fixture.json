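{
 "sym": {
  "x_even": [
   0.0012301533574825742,
   0.2987455375084699,
   -0.2741378553622176,
   -0.8905918387572742,
   -0.45467078517172255,
   -0.9916465549964624,
   0.060143602597438485,
   1.3402152455545335,
   -0.49220651855132963,
   -0.6204748998199404,
   0.4898420501851982,
   0.35688700816006075,
   0.10541424899789856,
   -0.9304680447082047,
   -0.02925182246327349,
   0.6953031944582878,
   -1.344214547285082,
   -0.45761576104021817,
   -1.901222739800844,
   -1.289537739784976,
   -1.8417350377917323,
   -0.23509113107468127
  ],
  "cA_even": [
   -0.733050750740394,
   0.9098650789597627,
   -0.6058222467803174,
   -1.035317529608444,
   -0.08236121878817056,
   0.25990029057100134,
   -0.0650002991645292,
   -1.5892205390328955,
   0.5319829175274912,
   -0.35668911637171347,
   0.5252337728453099,
   -0.3946772293670904,
   0.07283414820152688,
   -0.48662181852706093,
   -2.0527136673474256,
   -1.8613377422092865,
   -0.8407709105570275
  ],
  "cD_even": [
   0.21622968553815086,
   -0.3777566475060287,
   0.49439017062177587,
   0.33799040450840834,
   -1.0846014143773812,
   0.568120942061233,
   -0.004175846907017058,
   0.6689297399523535,
   -1.195777028573058,
   -0.7544163378668618,
   -0.5242696703985386,
   -0.4395329801750453,
   1.1810640610666507,
   0.34843631840389705,
   1.2064634308534445,
   -0.15548151301539787,
   -0.5406013521474095
  ],
  "x_odd": [
   -1.2674464814437032,
   0.2712643588217015,
   0.15675108662422516,
   -0.18693094462995438,
   -2.516759710820513,
   -0.5386928958466366,
   -0.048500945401071985,
   0.11330898600330756,
   -1.5301357655053935,
   -0.47775327603393064,
   -0.9785190780566395,
   -0.8088372394255993,
   1.0608986233860787,
   -0.8075346753318965,
   -0.0325217049455206,
   0.8843898673831739,
   -0.583600432743302,
   -0.11170194958415963,
   0.11046414324948059,
   0.06378177425506196,
   -1.2250558264176934,
   0.0761402303770081,
   1.3588234217415376,
   -1.5471446781284823,
   0.8593826880215982,
   0.11935402569658124,
   -0.6414703941072214,
   2.000416546342423,
   0.7622597120847118,
   -1.1992889021052233,
   0.07451622877146342,
   0.5766895836701853,
   -0.1887821253507493,
   0.682910267195206,
   -0.06651732014941557,
   0.6672475608343279,
   1.438522591656152
  ],
  "wavedec3": {
   "cA3": [
    -1.7156874205832602,
    -1.4617037581289896,
    -2.3240579745287415,
    -1.6466797897759444,
    -1.6093483440398995,
    -1.9551795043590752,
    -1.3671028741832643,
    -2.0598193104795914,
    -1.9511766775438777,
    -1.7247826435056863,
    -1.5083230121263826,
    -0.4639651807393532,
    0.13104198667462846,
    0.9491598195243351,
    2.9092467401141135,
    2.469861434402625
   ],
   "cD3": [
    -0.05106174011419066,
    0.43578586808473896,
    0.212060190306783,
    -0.06706842164133002,
    -0.2938337321097591,
    -0.031754205251647634,
    -0.718061039400999,
    0.9531634736198017,
    0.3354581069021186,
    -0.47058137995585925,
    0.2930072254820406,
    0.032046470726379755,
    -0.9988412961409386,
    0.20988347880442815,
    0.6930110435176313,
    -0.22491274130936348
   ],
   "cD2": [
    0.5322129999141264,
    -1.6463703340618565,
    0.4883685574751575,
    1.47057270905301,
    1.6993131378696025,
    -0.2416116904069185,
    -0.17832997181358734,
    0.6542050076114806,
    0.366201542250534,
    0.463403246518026,
    -0.26401871321421616,
    -0.678021647322617,
    -0.8576486644705721,
    0.6699189771015854,
    0.8691970930373815,
    0.2510384673243376,
    -0.3670536153466218,
    -0.4893991001734947,
    -0.43122061521784927
   ],
   "cD1": [
    0.7415676200438334,
    -1.0749654660227927,
    -0.2705125457431766,
    -1.0606084597729983,
    -0.11511286009524932,
    -0.8486777589428298,
    0.8993605558540663,
    1.0295019150376399,
    -1.2540429861939433,
    0.11476411829417714,
    -0.4773005010177519,
    0.01656001132550956,
    2.3809128359518517,
    -0.7213324837636107,
    -1.297739752912014,
    1.626851253162267,
    -1.0412184143516063,
    -0.36840656601248545,
    -0.03697562339595208,
    -0.016851694234987495,
    0.4992496599438735,
    0.5545593227684369,
    -0.4163294812119142,
    -0.3558193117097979,
    1.793177107379019
   ]
  }
 },
 "per": {
  "x_even": [
   0.0012301533574825742,
   0.2987455375084699,
   -0.2741378553622176,
   -0.8905918387572742,
   -0.45467078517172255,
   -0.9916465549964624,
   0.060143602597438485,
   1.3402152455545335,
   -0.49220651855132963,
   -0.6204748998199404,
   0.4898420501851982,
   0.35688700816006075,
   0.10541424899789856,
   -0.9304680447082047,
   -0.02925182246327349,
   0.6953031944582878,
   -1.344214547285082,
   -0.45761576104021817,
   -1.901222739800844,
   -1.289537739784976,
   -1.8417350377917323,
   -0.23509113107468127
  ],
  "cA_even": [
   -1.9168612479511273,
   -2.235399520374678,
   -0.00045120025300443567,
   -0.0650002991645292,
   -1.5892205390328955,
   0.5319829175274912,
   -0.35668911637171347,
   0.5252337728453099,
   -0.3943458778942951,
   0.07524780794154427,
   -0.517788756842364
  ],
  "cD_even": [
   0.37666072912671167,
   -1.0847417094433534,
   0.5669380584979061,
   -0.004175846907017058,
   0.6689297399523535,
   -1.195777028573058,
   -0.7544163378668618,
   -0.5242696703985386,
   -0.5124631083834054,
   0.05535682494832979,
   0.3173729201908972
  ],
  "x_odd": [
   -1.2674464814437032,
   0.2712643588217015,
   0.15675108662422516,
   -0.18693094462995438,
   -2.516759710820513,
   -0.5386928958466366,
   -0.048500945401071985,
   0.11330898600330756,
   -1.5301357655053935,
   -0.47775327603393064,
   -0.9785190780566395,
   -0.8088372394255993,
   1.0608986233860787,
   -0.8075346753318965,
   -0.0325217049455206,
   0.8843898673831739,
   -0.583600432743302,
   -0.11170194958415963,
   0.11046414324948059,
   0.06378177425506196,
   -1.2250558264176934,
   0.0761402303770081,
   1.3588234217415376,
   -1.5471446781284823,
   0.8593826880215982,
   0.11935402569658124,
   -0.6414703941072214,
   2.000416546342423,
   0.7622597120847118,
   -1.1992889021052233,
   0.07451622877146342,
   0.5766895836701853,
   -0.1887821253507493,
   0.682910267195206,
   -0.06651732014941557,
   0.6672475608343279,
   1.438522591656152
  ],
  "wavedec3": {
   "cA3": [
    -1.1521871271840662,
    -0.1853169963759682,
    0.003686745145764017,
    1.8888405103086994,
    -1.0037117438056717
   ],
   "cD3": [
    0.37355836094510975,
    -0.5424195156047104,
    0.020345732951578262,
    0.46248755017218135,
    -0.7590416369829457
   ],
   "cD2": [
    -1.1775629424066247,
    0.8169191609944043,
    -0.6088985976780437,
    -0.3035323073939742,
    -0.5547643849955821,
    -0.24895673072449898,
    0.7793604740755137,
    -0.6016232760182278,
    -1.7812927943797734,
    -1.1355294000022809
   ],
   "cD1": [
    -0.977514486278557,
    -0.14761172241114623,
    -0.8433896995717519,
    0.8993605558540663,
    1.0295019150376399,
    -1.2540429861939433,
    0.11476411829417714,
    -0.4773005010177519,
    0.01656001132550956,
    2.3809128359518517,
    -0.7213324837636107,
    -1.297739752912014,
    1.626851253162267,
    -1.0412184143516063,
    -0.36840656601248545,
    -0.03697562339595208,
    -0.8103309507058223,
    -0.8647097161288382,
    -0.3908551000595336
   ]
  }
 }
}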