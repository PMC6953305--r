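parent,subspecies,class,BRR,MRR,HRR,PCG,CAS,CD,GT,GC,AC
256A,indica,cms,0,0,1,0,2,0,0,0,3
Zhenpin A,indica,cms,0,0,1,0,4,0,0,0,7
257A,indica,cms,0,0,1,0,3,0,0,0,3
II-32A,indica,cms,0,0,1,0,1,0,0,0,1
Zhenshan 97A,indica,cms,0,0,1,0,4,0,0,0,4
Yuetai A,indica,cms,0,0,1,0,4,0,0,0,6
You 1A,indica,cms,0,0,1,0,1,0,0,0,1
Zhong 9A,indica,cms,0,0,0,0,3,0,0,0,3
Minghui 63,indica,restorer,0,0,1,0,6,0,0,0,8
Zhenhui 084,indica,restorer,1,1,1,0,5,0,0,1,7
Yanhui 559,indica,restorer,0,0,1,0,2,0,0,0,2
Huizi 04,indica,restorer,0,0,0,0,1,0,0,0,1
Hui 9368,indica,restorer,0,0,0,0,2,0,0,0,4
Kanghui98,indica,restorer,0,0,0,0,2,0,0,0,5
863A,japonica,cms,0,0,0,0,1,0,0,0,0
9201A,japonica,cms,0,0,0,0,2,0,0,0,2
Xu 2A,japonica,cms,0,0,0,0,0,0,0,0,0
Nanjing 46A,japonica,cms,0,0,0,0,1,0,0,0,1
731A,japonica,cms,0,0,0,0,0,0,0,0,0
Liuqianxin A,japonica,cms,0,0,0,0,2,0,0,0,2
6427A,japonica,cms,0,0,0,0,0,0,0,0,0
Zhendao 88A,japonica,cms,1,1,1,1,2,1,1,1,2
Qingkong A,japonica,cms,0,0,0,0,1,0,0,0,1
Yueguang A,japonica,cms,0,0,0,0,0,0,0,0,0
Wuqiang A,japonica,cms,0,0,0,0,2,0,0,0,2
Wuyujing 3A,japonica,cms,0,0,0,0,1,0,0,0,1
Liuyan 189A,japonica,cms,0,0,0,0,0,0,0,0,0
C418,japonica,restorer,0,0,1,0,1,0,0,0,3
Ninghui8hao,japonica,restorer,0,0,0,0,4,0,0,0,7
Yunhi 4 hao,japonica,restorer,0,0,1,0,1,0,0,0,1
Zhehui 315,japonica,restorer,0,0,1,0,2,0,0,0,4
Yanhui R50,japonica,restorer,2,2,2,1,6,1,1,2,9
Xiushui 04R,japonica,restorer,0,0,0,0,0,0,0,0,0
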