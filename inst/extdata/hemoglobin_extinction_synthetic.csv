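# Synthetic oxy-/deoxyhemoglobin molar extinction spectra, 650-1100 nm at 2 nm.
# Monotone-spline interpolation through smooth anchor values of literature
# magnitude; NOT a measured reference dataset. Units are arbitrary but
# mutually consistent (relative shapes are what spectral unmixing uses).
# Version: 1.0
wavelength_nm,eps_hbo2,eps_hb
650,368,3750
652,358.05,3643.94
654,347.74,3536.43
656,337.62,3429.65
658,328.19,3325.78
660,320,3227
662,313.3,3134.07
664,307.73,3045.54
666,302.91,2960.26
668,298.46,2877.13
670,294,2795
672,289.26,2714.07
674,284.51,2635.1
676,280.13,2557.78
678,276.5,2481.85
680,274,2407
682,272.8,2332.17
684,272.64,2257.54
686,273.28,2184.74
688,274.48,2115.35
690,276,2051
692,277.87,1993.22
694,280.26,1940.93
696,283.1,1891.83
698,286.37,1843.62
700,290,1794
702,294.1,1743.68
704,298.69,1694.2
706,303.63,1644.48
708,308.78,1593.44
710,314,1540
712,319.02,1481.02
714,323.95,1417.23
716,329.17,1353.33
718,335.06,1294.02
720,342,1244
722,350.19,1203.25
724,359.38,1168.62
726,369.26,1140.18
728,379.57,1117.95
730,390,1102
732,400.43,1090.42
734,411.06,1083.17
736,422.06,1083.11
738,433.65,1093.1
740,446,1116
742,459.44,1156.58
744,473.84,1212.95
746,488.72,1277.93
748,503.6,1344.34
750,518,1405
752,531.92,1469.54
754,545.68,1542.73
756,559.28,1610.15
758,572.72,1657.38
760,586,1670
762,599.12,1635.98
764,612.08,1564.95
766,624.88,1474.93
768,637.52,1383.94
770,650,1310
772,662.42,1254.14
774,674.77,1204.35
776,686.91,1159.09
778,698.7,1116.82
780,710,1076
782,720.54,1037.15
784,730.43,1001.3
786,740.05,967.66
788,749.78,935.49
790,760,904
792,770.94,872.11
794,782.35,840.34
796,793.89,810.3
798,805.22,783.65
800,816,762
802,826.18,746.62
804,835.97,736.43
806,845.47,729.53
808,854.78,724.02
810,864,718
812,872.7,710.98
814,880.83,704.23
816,889.01,698.49
818,897.86,694.5
820,908,693
822,920.08,693
824,933.68,693
826,947.84,693
828,961.6,693
830,974,693
832,984.94,693
834,995.07,693
836,1004.53,693
838,1013.46,693
840,1022,693
842,1029.81,692.68
844,1036.78,691.96
846,1043.46,691.2
848,1050.35,690.76
850,1058,691
852,1066.9,692.03
854,1076.69,693.62
856,1086.63,695.58
858,1095.98,697.77
860,1104,700
862,1110.73,701.7
864,1116.78,702.64
866,1122.28,703.18
868,1127.31,703.68
870,1132,704.5
872,1136.45,706
874,1140.76,708.54
876,1145.06,712.48
878,1149.43,718.18
880,1154,726
882,1158.56,736.64
884,1162.9,750.11
886,1167.07,765.75
888,1171.17,782.9
890,1175.25,800.88
892,1179.39,819.02
894,1183.67,836.68
896,1188.14,853.17
898,1192.9,867.83
900,1198,880
902,1203.87,889.93
904,1210.67,898.44
906,1218.07,905.75
908,1225.76,912.05
910,1233.42,917.54
912,1240.72,922.43
914,1247.35,926.92
916,1252.99,931.21
918,1257.31,935.5
920,1260,940
922,1261.3,944.75
924,1261.71,949.63
926,1261.31,954.56
928,1260.17,959.46
930,1258.37,964.26
932,1255.98,968.88
934,1253.06,973.25
936,1249.71,977.29
938,1245.98,980.92
940,1241.96,984.07
942,1237.72,986.67
944,1233.33,988.64
946,1228.86,989.9
948,1224.39,990.38
950,1220,990
952,1215.32,988.36
954,1210.03,985.28
956,1204.24,981.02
958,1198.08,975.84
960,1191.67,970
962,1185.12,963.76
964,1178.56,957.38
966,1172.11,951.12
968,1165.88,945.24
970,1160,940
972,1154.4,935.21
974,1148.91,930.51
976,1143.52,925.88
978,1138.21,921.3
980,1132.96,916.76
982,1127.76,912.24
984,1122.58,907.73
986,1117.42,903.21
988,1112.24,898.66
990,1107.04,894.07
992,1101.79,889.43
994,1096.48,884.72
996,1091.09,879.92
998,1085.6,875.02
1000,1080,870
1002,1074.22,864.86
1004,1068.24,859.6
1006,1062.09,854.24
1008,1055.79,848.8
1010,1049.38,843.28
1012,1042.88,837.7
1014,1036.33,832.07
1016,1029.76,826.4
1018,1023.2,820.71
1020,1016.67,815
1022,1010.2,809.29
1024,1003.84,803.6
1026,997.6,797.93
1028,991.52,792.3
1030,985.62,786.72
1032,979.95,781.2
1034,974.52,775.76
1036,969.36,770.4
1038,964.51,765.14
1040,960,760
1042,955.78,754.94
1044,951.76,749.94
1046,947.95,744.99
1048,944.33,740.08
1050,940.88,735.22
1052,937.6,730.4
1054,934.48,725.62
1056,931.5,720.87
1058,928.65,716.16
1060,925.93,711.48
1062,923.31,706.83
1064,920.8,702.2
1066,918.38,697.59
1068,916.03,693.01
1070,913.75,688.44
1072,911.53,683.88
1074,909.35,679.34
1076,907.2,674.8
1078,905.08,670.27
1080,902.96,665.74
1082,900.85,661.21
1084,898.73,656.68
1086,896.58,652.14
1088,894.4,647.6
1090,892.18,643.04
1092,889.9,638.47
1094,887.55,633.89
1096,885.13,629.28
1098,882.61,624.65
1100,880,620
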