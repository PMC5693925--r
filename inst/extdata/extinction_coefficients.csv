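# Chromophore extinction / absorption table for near-infrared tissue oximetry.
# eps_hbo, eps_hbr: extinction coefficients of oxy- and deoxyhemoglobin in
#   cm^-1 per uM, natural-log (Napierian) base, i.e. already multiplied by
#   ln(10) and scaled from the molar (cm^-1/M, log10) compilation values.
#   Source: standard literature compendium of hemoglobin spectra
#   (Gratzer/Kollias compilation), linearly interpolated to the instrument
#   wavelengths; values approximate to ~2%.
# mua_water: absorption coefficient of pure water, cm^-1 (Hale & Querry
#   survey), linearly interpolated.
# Covers the 8 FDNIRS wavelengths and the 850 nm DCS wavelength.
wavelength_nm,eps_hbo,eps_hbr,mua_water
672,0.000737,0.006102,0.0040
689,0.000668,0.005020,0.0047
701,0.000691,0.004283,0.0062
724,0.000898,0.003016,0.0148
771,0.001497,0.003178,0.0258
783,0.001704,0.002464,0.0249
803,0.001957,0.001796,0.0215
829,0.002256,0.001612,0.0282
850,0.002441,0.001589,0.0434
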