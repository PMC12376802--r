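id,asthma,feno,ige,bec,prick,sex,weight,fev1_pct
S00001,FALSE,24.8440007182743,21.3813859582218,92.4776285798491,FALSE,female,71.9291102645524,140.92989999356
S00002,FALSE,19.0847657641702,48.2091602312554,72.4404924227227,FALSE,male,63.1872995613603,128.355933944606
S00003,FALSE,14.1904784487003,3.00582177713017,90.4714686344039,FALSE,male,76.0786197016386,126.456215577995
S00004,FALSE,13.4458007689011,21.5722367784289,55.8336922442238,FALSE,male,63.1820456421313,140.812882569946
S00005,FALSE,27.1972761412081,5.60832043359543,248.602183088198,FALSE,female,62.4857578188151,117.978793743284
S00006,FALSE,29.1397112421671,17.3357680279011,120.103119593168,FALSE,female,51.7595600228568,128.4704236504
S00007,FALSE,19.7423950794113,14.4479922667146,265.901228087674,FALSE,male,63.9298161985885,131.018557160848
S00008,FALSE,14.0521562398196,81.5858428954724,137.104712640286,FALSE,female,58.2741593881445,99.7346260307929
S00009,FALSE,7.99384219006742,14.5404870316434,388.804877518661,FALSE,female,66.4172551544773,115.375703013597
S00010,FALSE,8.43057850137204,35.7561802269906,243.03884398597,FALSE,male,54.2915565486459,150.227481487
S00011,FALSE,6.35323207876694,33.9130560156185,197.721169136787,FALSE,female,54.0902872936816,133.795493861151
S00012,FALSE,19.0867554737241,14.6842710853247,156.650015833078,FALSE,female,59.8408940958317,105.028853279304
S00013,FALSE,23.0036979793628,13.5209313106723,402.232824866166,FALSE,female,71.8151393813554,73.7933390189298
S00014,FALSE,17.4373371279322,37.1878048585164,128.89478339918,FALSE,male,55.4280755157165,120.708120481805
S00015,FALSE,2.78882785297537,9.96163810908009,38.94219070863,FALSE,male,67.568704319462,111.627608968089
S00016,FALSE,13.9007992600879,23.9857915733589,221.381185266781,FALSE,female,58.9531187413958,105.810759346862
S00017,FALSE,9.30190354196677,39.7988291233719,191.891818280372,FALSE,female,66.5040371585531,120.179143564695
S00018,FALSE,18.9430955241928,177.669127701712,35.9816782035845,FALSE,male,84.6988776327207,140.866871906165
S00019,FALSE,6.57176784562312,7.17245538911313,289.186112743393,FALSE,female,56.82698644255,115.963228633285
S00020,FALSE,5.33609617219,27.5030293678398,64.5155525469005,FALSE,male,52.8915066642823,115.936160272091
S00021,FALSE,26.9452027804723,33.6301660082068,169.246904173926,FALSE,female,71.9088559017675,138.336501876861
S00022,FALSE,17.6417471972252,47.4084638209441,146.922682644261,FALSE,female,69.687583701825,110.558764844761
S00023,FALSE,25.631303737593,46.0288065611918,158.764979970855,TRUE,female,62.801000122506,106.949733285601
S00024,FALSE,13.4450800024117,171.940279082875,114.559466645555,FALSE,female,72.169117962453,117.959373672721
S00025,FALSE,18.3952521775062,13.7450087588603,348.280138005902,FALSE,male,52.3884399479249,91.3280232614414
S00026,FALSE,6.7860839825868,11.0988251027735,217.000540016891,FALSE,female,57.3390169989409,133.487553061625
S00027,TRUE,39.9413074144294,16.0355019445211,18.9545075329709,TRUE,female,80.0184401929031,97.4563424679658
S00028,TRUE,17.8082140679148,145.519437302816,166.098937560623,TRUE,female,85.0251006783277,113.138627969167
S00029,TRUE,26.7721726306148,293.919044217857,142.091893335202,FALSE,male,84.6330566102214,122.106771234521
S00030,TRUE,17.1425423167775,399.167671045472,172.175034079627,TRUE,female,70.6648259268044,100.321045713408
S00031,TRUE,21.351121928661,151.27146998728,153.775254582258,FALSE,female,55.5528877264079,108.249496388856
S00032,TRUE,22.6719651576018,386.439379953325,75.036585871971,TRUE,male,62.4063975879064,112.103831257435
S00033,TRUE,28.7847354223897,132.699835033006,219.808688976938,TRUE,female,80.4300706880499,118.481441172427
S00034,TRUE,29.5759592004988,1602.91494463711,72.4110478562914,TRUE,male,73.3956985186924,91.7950842991808
S00035,TRUE,21.0729102385369,5.56598902312045,286.981016959775,TRUE,female,64.9355691943321,91.3209380436605
S00036,TRUE,25.053206011381,67.904554697491,119.900190216425,FALSE,male,52.3530310051699,106.133587572794
S00037,TRUE,17.7528778234137,130.334809287839,104.934874106195,TRUE,male,60.8392892191997,112.167629867046
S00038,TRUE,24.8979565280604,23.1827572810623,111.868962980903,FALSE,male,71.4567470925697,98.0600483374026
S00039,TRUE,21.6698922147965,89.8447290334792,128.244500237157,TRUE,female,81.6447305257214,101.361942242671
S00040,TRUE,24.6992470362017,277.018635412145,104.189671332713,FALSE,male,76.1169946842231,115.90876745479
S00041,TRUE,16.2213022714984,16.8317596922081,147.645702373181,TRUE,female,90.729477647856,121.418679230803
S00042,TRUE,17.7705240958171,24.0220425399176,93.3538423220744,TRUE,female,75.9059776504969,109.418270541657
S00043,TRUE,25.3470944995723,82.5805148580678,163.276211306891,TRUE,male,80.9352665025647,103.564378409286
S00044,TRUE,27.3745471280191,227.792884477216,260.938420157696,TRUE,male,67.9065279099481,112.21247963631
S00045,TRUE,17.8543777528493,122.666992710707,169.666991084454,FALSE,female,62.8729896834668,106.588264034383
S00046,TRUE,16.1947302673547,26.1280120710706,95.5446852477099,TRUE,male,73.8311947922655,118.545128702808
S00047,TRUE,23.2531686277821,146.323587427922,86.6085657568438,FALSE,male,87.2629953051677,108.791269665556
S00048,TRUE,16.6151924117118,31.1315061215375,107.766588003756,TRUE,female,105.931512406175,90.6807468283411
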