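site_id,pH,ec,cec,oc,caco3,ox_mn,cd_mn,cd_fe
Haikou,4.93,110.8,8.75,1.5,0.25,200,574,83920
Qiyang,5.31,74.1,7.47,0.9,0.25,294,422,26154
Hailun,6.56,153,33.6,3,0.25,451,396,6559
Jiaxing,6.7,158.8,19.3,1.4,0.25,261,297,10824
Hangzhou,6.8,203.3,12.83,2.5,0.25,135,153,8413
Chongqing,7.12,71,22.3,1,0.25,283,315,7727
Guangzhou,7.27,136.7,8.3,1.5,0.15,33,48,11411
Lingshan,7.48,92.5,22.6,4.3,4.27,267,276,6950
Hulunber,7.66,888,22.7,2.7,0.27,307,322,5259
Gongzhuling,7.82,146.9,28.7,2.2,0.27,387,366,6932
Shijiazhuang,8.19,302,11.7,1,3.84,222,261,7544
Urumchi,8.72,226.5,10.3,0.9,5.08,251,305,4795
Yangling,8.83,83.2,8.46,0.6,8.92,288,350,7193
Langfang,8.84,5.7,6.36,0.6,2.42,74,112,3729
Zhangye,8.86,108.7,8.08,1,7.75,121,166,4289
Zhengzhou,8.86,151.8,8.5,1.6,0.15,233,331,8356
Dezhou,8.9,111.8,8.33,0.7,6.17,145,219,4965
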