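"feature","category","provenance"
"firstorder_energy","first_order","standard"
"firstorder_total_energy","first_order","standard"
"firstorder_entropy","first_order","standard"
"firstorder_minimum","first_order","standard"
"firstorder_p10","first_order","standard"
"firstorder_p90","first_order","standard"
"firstorder_maximum","first_order","standard"
"firstorder_mean","first_order","standard"
"firstorder_median","first_order","standard"
"firstorder_interquartile_range","first_order","standard"
"firstorder_range","first_order","standard"
"firstorder_mean_absolute_deviation","first_order","standard"
"firstorder_robust_mean_absolute_deviation","first_order","standard"
"firstorder_root_mean_squared","first_order","standard"
"firstorder_skewness","first_order","standard"
"firstorder_kurtosis","first_order","standard"
"firstorder_variance","first_order","standard"
"firstorder_uniformity","first_order","standard"
"shape_mesh_volume","shape","standard"
"shape_voxel_volume","shape","standard"
"shape_surface_area","shape","standard"
"shape_surface_volume_ratio","shape","standard"
"shape_sphericity","shape","standard"
"shape_maximum_3d_diameter","shape","standard"
"shape_maximum_2d_diameter_slice","shape","standard"
"shape_maximum_2d_diameter_column","shape","standard"
"shape_maximum_2d_diameter_row","shape","standard"
"shape_major_axis_length","shape","standard"
"shape_minor_axis_length","shape","standard"
"shape_least_axis_length","shape","standard"
"shape_elongation","shape","standard"
"shape_flatness","shape","standard"
"glcm_autocorrelation","glcm","standard"
"glcm_joint_average","glcm","standard"
"glcm_cluster_prominence","glcm","standard"
"glcm_cluster_shade","glcm","standard"
"glcm_cluster_tendency","glcm","standard"
"glcm_contrast","glcm","standard"
"glcm_correlation","glcm","standard"
"glcm_difference_average","glcm","standard"
"glcm_difference_entropy","glcm","standard"
"glcm_difference_variance","glcm","standard"
"glcm_inverse_difference","glcm","standard"
"glcm_inverse_difference_moment","glcm","standard"
"glcm_idmn","glcm","standard"
"glcm_idn","glcm","standard"
"glcm_imc1","glcm","standard"
"glcm_imc2","glcm","standard"
"glcm_inverse_variance","glcm","standard"
"glcm_joint_energy","glcm","standard"
"glcm_joint_entropy","glcm","standard"
"glcm_mcc","glcm","standard"
"glcm_maximum_probability","glcm","standard"
"glcm_sum_average","glcm","standard"
"glcm_sum_entropy","glcm","standard"
"glcm_sum_squares","glcm","standard"
"glszm_small_area_emphasis","glszm","standard"
"glszm_large_area_emphasis","glszm","standard"
"glszm_gray_level_nonuniformity","glszm","standard"
"glszm_gray_level_nonuniformity_normalized","glszm","standard"
"glszm_size_zone_nonuniformity","glszm","standard"
"glszm_size_zone_nonuniformity_normalized","glszm","standard"
"glszm_zone_percentage","glszm","standard"
"glszm_gray_level_variance","glszm","standard"
"glszm_zone_variance","glszm","standard"
"glszm_zone_entropy","glszm","standard"
"glszm_low_gray_level_zone_emphasis","glszm","standard"
"glszm_high_gray_level_zone_emphasis","glszm","standard"
"glszm_small_area_low_gray_level_emphasis","glszm","standard"
"glszm_small_area_high_gray_level_emphasis","glszm","standard"
"glszm_large_area_low_gray_level_emphasis","glszm","standard"
"glszm_large_area_high_gray_level_emphasis","glszm","standard"
"cdf_auc","cdf","reconstructed"
"cdf_mean_minus_median","cdf","reconstructed"
"cdf_central_slope","cdf","reconstructed"
"cdf_lower_tail_fraction","cdf","reconstructed"
"cdf_upper_tail_fraction","cdf","reconstructed"
"physical_volume_ml","physical","reconstructed"
"physical_mass_g","physical","reconstructed"
"fractal_mask_dimension","fractal","reconstructed"
"fractal_boundary_dimension","fractal","reconstructed"
"fractal_intensity_dimension","fractal","reconstructed"
"fractal_lacunarity_2","fractal","reconstructed"
"fractal_lacunarity_4","fractal","reconstructed"
"fractal_lacunarity_8","fractal","reconstructed"
"fractal_levelset_dimension_q25","fractal","reconstructed"
"fractal_levelset_dimension_q50","fractal","reconstructed"
"fractal_levelset_dimension_q75","fractal","reconstructed"
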