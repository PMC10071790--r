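# SYNTHETIC S-value matrix for a 70-kg adult phantom (mGy per MBq.h).
# Plausible magnitudes for demonstration and testing only; not derived
# from any published phantom library.
source,target,mGy_per_MBq_h
liver,liver,0.1657
liver,spleen,0.003294
liver,kidneys,0.002555
liver,lungs,0.001591
liver,red_marrow,0.001605
liver,muscle,0.0005283
liver,colon,0.002402
liver,stomach,0.003294
liver,breast,0.002162
liver,gonads,0.005483
liver,bladder,0.004839
liver,oesophagus,0.005232
liver,thyroid,0.006669
liver,bone_surface,0.003562
liver,brain,0.001489
liver,salivary_glands,0.004019
liver,skin,0.001117
spleen,liver,0.003294
spleen,spleen,0.9434
spleen,kidneys,0.006097
spleen,lungs,0.003797
spleen,red_marrow,0.003831
spleen,muscle,0.001261
spleen,colon,0.005731
spleen,stomach,0.007861
spleen,breast,0.005158
spleen,gonads,0.01308
spleen,bladder,0.01155
spleen,oesophagus,0.01249
spleen,thyroid,0.01591
spleen,bone_surface,0.0085
spleen,brain,0.003553
spleen,salivary_glands,0.00959
spleen,skin,0.002665
kidneys,liver,0.002555
kidneys,spleen,0.006097
kidneys,kidneys,0.5675
kidneys,lungs,0.002945
kidneys,red_marrow,0.002971
kidneys,muscle,0.0009779
kidneys,colon,0.004445
kidneys,stomach,0.006097
kidneys,breast,0.004001
kidneys,gonads,0.01015
kidneys,bladder,0.008957
kidneys,oesophagus,0.009684
kidneys,thyroid,0.01234
kidneys,bone_surface,0.006593
kidneys,brain,0.002756
kidneys,salivary_glands,0.007439
kidneys,skin,0.002067
lungs,liver,0.001591
lungs,spleen,0.003797
lungs,kidneys,0.002945
lungs,lungs,0.22
lungs,red_marrow,0.00185
lungs,muscle,0.0006089
lungs,colon,0.002768
lungs,stomach,0.003797
lungs,breast,0.002491
lungs,gonads,0.006319
lungs,bladder,0.005577
lungs,oesophagus,0.00603
lungs,thyroid,0.007686
lungs,bone_surface,0.004105
lungs,brain,0.001716
lungs,salivary_glands,0.004632
lungs,skin,0.001287
red_marrow,liver,0.001605
red_marrow,spleen,0.003831
red_marrow,kidneys,0.002971
red_marrow,lungs,0.00185
red_marrow,red_marrow,0.224
red_marrow,muscle,0.0006143
red_marrow,colon,0.002793
red_marrow,stomach,0.003831
red_marrow,breast,0.002513
red_marrow,gonads,0.006375
red_marrow,bladder,0.005627
red_marrow,oesophagus,0.006084
red_marrow,thyroid,0.007754
red_marrow,bone_surface,0.004142
red_marrow,brain,0.001731
red_marrow,salivary_glands,0.004673
red_marrow,skin,0.001298
muscle,liver,0.0005283
muscle,spleen,0.001261
muscle,kidneys,0.0009779
muscle,lungs,0.0006089
muscle,red_marrow,0.0006143
muscle,muscle,0.02426
muscle,colon,0.0009191
muscle,stomach,0.001261
muscle,breast,0.0008272
muscle,gonads,0.002098
muscle,bladder,0.001852
muscle,oesophagus,0.002002
muscle,thyroid,0.002552
muscle,bone_surface,0.001363
muscle,brain,0.0005699
muscle,salivary_glands,0.001538
muscle,skin,0.0004273
remainder,liver,0.003
remainder,spleen,0.003
remainder,kidneys,0.003
remainder,lungs,0.003
remainder,red_marrow,0.003
remainder,muscle,0.003
remainder,colon,0.003
remainder,stomach,0.003
remainder,breast,0.003
remainder,gonads,0.003
remainder,bladder,0.003
remainder,oesophagus,0.003
remainder,thyroid,0.003
remainder,bone_surface,0.003
remainder,brain,0.003
remainder,salivary_glands,0.003
remainder,skin,0.003
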