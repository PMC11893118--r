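date,tmin,tmax,radiation,rain,vp
20210101,18.4,32.1,22.7,41.1,21.2
20210102,24.2,33.4,24.4,0,30.2
20210103,20.7,30.3,24.3,0,24.3
20210104,21.5,30.7,30,6.6,25.6
20210105,23.3,35.8,30,4.4,28.5
20210106,22.7,31.6,27.5,0,27.6
20210107,29,36.1,26.3,0,39.9
20210108,27.4,34.7,24.6,2.4,36.4
20210109,21.3,33.4,28.9,0,25.3
20210110,20.4,31.5,26.9,0,23.9
20210111,21.3,31.8,22.8,0,25.3
20210112,21.2,32.8,26.2,0,25.1
20210113,21.1,30.4,24.5,0,24.9
20210114,22.7,33,25,0,27.5
20210115,18.1,31.2,28.3,18.6,20.7
20210116,22.8,33.5,25.4,0,27.7
20210117,19.7,33.1,26.2,1.8,22.9
20210118,24.3,35.3,27.2,0,30.2
20210119,21.9,32.3,25.4,5,26.2
20210120,21.6,32.2,26.5,4.3,25.7
20210121,22.6,32.1,26.7,0,27.4
20210122,23.6,33.4,24.1,0,29
20210123,23.9,32.6,23.9,0,29.7
20210124,24.3,34.1,25.4,0,30.2
20210125,20.9,33.6,26.2,0,24.6
20210126,25,33.4,23.7,0,31.6
20210127,20.5,33,25.6,0,24.1
20210128,23.6,31.8,28.4,0,29.1
20210129,24.1,32.9,26.1,0,30
20210130,23.1,31.3,26,5.6,28.3
20210131,20.4,31,23.9,10.4,23.8
20210201,20.7,31.3,24.4,0,24.3
20210202,25.4,34.5,20.9,17.8,32.3
20210203,18.1,30,26,9.9,20.7
20210204,25.4,31.4,25.8,5.1,32.4
20210205,23,34,26.9,0,28.1
20210206,21.4,32.7,21.8,0,25.4
20210207,25.3,36.1,22.4,4.7,32.1
20210208,20.2,31.7,29.8,11.7,23.6
20210209,22.4,32.2,20.9,2.7,27
20210210,19,29.6,22.2,0,22
20210211,21.4,32.9,26.5,6.6,25.4
20210212,25.8,34.5,26,11.4,33.1
20210213,20.6,31,24,0,24.2
20210214,24.8,34.4,27,0,31.2
20210215,27,31.9,24,12.8,35.5
20210216,21.1,28.2,22.1,0,25
20210217,21.3,34.2,23.5,0,25.2
20210218,23.7,33.9,24.7,0,29.3
20210219,24.3,32.8,24.5,0,30.2
20210220,24.7,33.9,25.1,18,31
20210221,24.6,31.8,24.2,0,30.8
20210222,17.5,30.5,26.4,0,20
20210223,24.4,33.1,24.4,0,30.4
20210224,23.3,32.3,23.5,0,28.6
20210225,22.6,33,25.3,0,27.3
20210226,20.3,31.6,25.7,0,23.8
20210227,21.1,32.7,24.6,0,25
20210228,22.1,34.7,23.3,0,26.6
20210301,18.7,31.8,24.7,0,21.5
20210302,20.8,29.9,22.2,0,24.6
20210303,27,36.2,26.2,0,35.6
20210304,19,31.2,26.7,0,21.9
20210305,15.9,27.4,25.2,0,18.1
20210306,24.7,32.3,20.8,0.3,31
20210307,23.1,34.5,22.9,0,28.2
20210308,17.4,29.5,23.4,0,19.9
20210309,20.2,28.8,24.4,3.3,23.6
20210310,17.1,29.7,22.3,0,19.5
20210311,21.5,32.3,19.6,0,25.6
20210312,21.4,31.6,24.1,0,25.4
20210313,20.6,30.4,25.6,6.2,24.2
20210314,19.2,29,20.9,0,22.2
20210315,19.5,30.9,18.3,0,22.7
20210316,20.3,32.6,25.2,0,23.7
20210317,20,30.6,21.8,0,23.3
20210318,18.3,28.8,24.3,0,21
20210319,21.6,30.9,19.3,0,25.7
20210320,14,27.8,21.4,2.1,16
20210321,18.9,30.6,21.6,6.7,21.8
20210322,21.1,29.6,20.1,0,24.9
20210323,19.9,30.3,21.4,0,23.1
20210324,13.7,28.3,24.2,0,15.7
20210325,17.7,27.6,22.8,0,20.2
20210326,19.6,33.9,21.9,0,22.7
20210327,17.2,28,23.1,0,19.6
20210328,15.8,26.5,24.3,21.5,17.9
20210329,22.3,30,23.5,6.7,26.8
20210330,14.7,27.2,21,2.1,16.7
20210331,16.9,25.8,23.1,0,19.2
20210401,22.5,31.1,23.9,0,27.2
20210402,17.3,26.5,22,0,19.7
20210403,23.4,30.4,19.9,0,28.8
20210404,19.1,27.3,24.5,1.9,22.1
20210405,21.7,29.3,21.2,0,25.8
20210406,14.3,27.4,21.2,12,16.3
20210407,20.1,30.7,20.5,0,23.5
20210408,16.1,25.6,16.7,0,18.3
20210409,16.8,30.6,19.7,0,19.1
20210410,14.3,26.5,19.1,0,16.3
20210411,15.7,26.7,22.3,0,17.8
20210412,17.4,28,17.4,0,19.8
20210413,19.9,28.6,21.8,21.2,23.1
20210414,19.4,27,13.7,0,22.4
20210415,12.6,23,21.2,0,14.6
20210416,16.6,28.2,19.5,0,18.9
20210417,19,27.9,20.2,0,22
20210418,13.4,24.8,16.9,0,15.4
20210419,18,29.2,15.4,26.9,20.6
20210420,18,28.8,22.7,0,20.6
20210421,18.4,28.2,16,0,21.1
20210422,14.7,29.6,19.8,0,16.6
20210423,16.4,27.1,21.4,27.8,18.6
20210424,8.6,21.5,20.5,0,11.2
20210425,13,25.9,18.1,0,14.9
20210426,15.6,24.9,16.4,0,17.7
20210427,11.1,25,16.7,0,13.2
20210428,16.3,26.3,15.7,0,18.5
20210429,14.4,25.5,18.1,5.3,16.4
20210430,17.6,25.7,18.6,0,20.1
20210501,18.5,30.3,14.1,0,21.2
20210502,12.8,24,18.6,0,14.8
20210503,22.4,27.6,17.5,0,27
20210504,17.7,26.5,18.3,0,20.1
20210505,12.4,24.5,18,0,14.4
20210506,16.8,27.7,14.2,0,19.1
20210507,14.7,27.3,15.9,0,16.7
20210508,12.5,25.8,14.5,0,14.4
20210509,18.4,27.1,16.2,0,21.1
20210510,11,22.7,16.9,0,13.1
20210511,12.8,24,15.7,0,14.7
20210512,9.3,21.8,17.3,0,11.7
20210513,13.9,24.8,17.8,0,15.9
20210514,11.4,21.9,12.9,0,13.5
20210515,12.4,22.9,17.1,0,14.4
20210516,15.9,23.7,16.5,0,18
20210517,9.2,23,12.5,7.4,11.6
20210518,11.9,19.1,14.4,0,13.9
20210519,13.4,23,14.4,0,15.4
20210520,10.2,24,15.9,9.4,12.4
20210521,7.7,20.2,13.6,22.5,10.5
20210522,14,24.3,17.2,0,16
20210523,9.9,20.1,16.2,4.4,12.2
20210524,13.3,22.5,14.9,0,15.2
20210525,12.5,22.8,17.2,0,14.5
20210526,16.1,23.4,16.7,13.3,18.2
20210527,13.5,23.6,14.9,1.1,15.4
20210528,15.4,26.8,17,0,17.4
20210529,9.9,22,12.5,0,12.1
20210530,13.4,23.3,14.1,0,15.4
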