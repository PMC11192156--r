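# Shared column vocabulary.
# The full measurement vector produced by measure_particle().
MEASUREMENT_COLUMNS <- c("Area", "X", "Y", "XM", "YM", "Perim", "BX", "BY",
                         "Width", "Height", "Major", "Minor", "Angle", "Circ",
                         "Feret", "IntDen", "Median", "Skew", "Kurt",
                         "RawIntDen", "FeretX", "FeretY", "FeretAngle",
                         "MinFeret", "AR", "Round", "Solidity")

# The 25 retained measurements (Skew and Kurt are excluded: they are missing
# on binary scans) plus the categorical collection Site = 26 predictors.
PREDICTOR_MEASUREMENTS <- setdiff(MEASUREMENT_COLUMNS, c("Skew", "Kurt"))
PREDICTORS_DEFAULT <- c(PREDICTOR_MEASUREMENTS, "Site")
POSITIONAL_PREDICTORS <- c("X", "Y", "XM", "YM", "BX", "BY", "FeretX", "FeretY")

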