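patient,location,volume_ml,activity_mbq
1,duodenum,13.9,1.3
2,lesser_curvature_stomach,35.5,33.1
3,duodenum,15.4,2.3
4,duodenum,15.3,3.7
5,gastric_fundus,9.6,7.4
6,falciform_ligament,9.2,0.2
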