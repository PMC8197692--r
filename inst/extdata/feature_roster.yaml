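version: 1.0
count: 133
features:
- suv_mean
- suv_max
- suv_min
- suv_median
- suv_sd
- suv_variance
- suv_energy
- suv_rms
- suv_entropy
- suv_mad
- suv_p10
- suv_p25
- suv_p75
- suv_p90
- suv_iqr
- suv_range
- suv_cov
- aucCSH
- skewness
- kurtosis
- shape_volume_ml
- shape_surface_mm2
- shape_sphericity
- shape_max_diameter_mm
- shape_compactness
- glcm_energy
- glcm_contrast
- glcm_correlation
- glcm_homogeneity
- glcm_entropy
- glcm_dissimilarity
- glcm_autocorrelation
- glcm_cluster_shade
- glcm_cluster_prominence
- glcm_max_probability
- glrlm_sre
- glrlm_lre
- glrlm_gln
- glrlm_rln
- glrlm_rp
- glrlm_lgre
- glrlm_hgre
- glrlm_srlge
- glrlm_srhge
- glrlm_glv
- glrlm_rlv
- glszm_sze
- glszm_lze
- glszm_gln
- glszm_zsn
- glszm_zp
- glszm_lgze
- glszm_hgze
- glszm_szhge
- glszm_glv
- glszm_zsv
- ngtdm_coarseness
- ngtdm_contrast
- ngtdm_busyness
- ngtdm_complexity
- ngtdm_strength
- WF_glcm_energy
- WF_glcm_contrast
- WF_glcm_correlation
- WF_glcm_homogeneity
- WF_glcm_entropy
- WF_glcm_dissimilarity
- WF_glcm_autocorrelation
- WF_glcm_cluster_shade
- WF_glcm_cluster_prominence
- WF_glcm_max_probability
- WF_glrlm_sre
- WF_glrlm_lre
- WF_glrlm_gln
- WF_glrlm_rln
- WF_glrlm_rp
- WF_glrlm_lgre
- WF_glrlm_hgre
- WF_glrlm_srlge
- WF_glrlm_srhge
- WF_glrlm_glv
- WF_glrlm_rlv
- WF_glszm_sze
- WF_glszm_lze
- WF_glszm_gln
- WF_glszm_zsn
- WF_glszm_zp
- WF_glszm_lgze
- WF_glszm_hgze
- WF_glszm_szhge
- WF_glszm_glv
- WF_glszm_zsv
- WF_ngtdm_coarseness
- WF_ngtdm_contrast
- WF_ngtdm_busyness
- WF_ngtdm_complexity
- WF_ngtdm_strength
- Q_glcm_energy
- Q_glcm_contrast
- Q_glcm_correlation
- Q_glcm_homogeneity
- Q_glcm_entropy
- Q_glcm_dissimilarity
- Q_glcm_autocorrelation
- Q_glcm_cluster_shade
- Q_glcm_cluster_prominence
- Q_glcm_max_probability
- Q_glrlm_sre
- Q_glrlm_lre
- Q_glrlm_gln
- Q_glrlm_rln
- Q_glrlm_rp
- Q_glrlm_lgre
- Q_glrlm_hgre
- Q_glrlm_srlge
- Q_glrlm_srhge
- Q_glrlm_glv
- Q_glrlm_rlv
- Q_glszm_sze
- Q_glszm_lze
- Q_glszm_gln
- Q_glszm_zsn
- Q_glszm_zp
- Q_glszm_lgze
- Q_glszm_hgze
- Q_glszm_szhge
- Q_glszm_glv
- Q_glszm_zsv
- Q_ngtdm_coarseness
- Q_ngtdm_contrast
- Q_ngtdm_busyness
- Q_ngtdm_complexity
- Q_ngtdm_strength
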