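# Pinned coordinate-transform matrices.
#
# Brett "mni2tal" piecewise-linear approximation (M. Brett, 1999;
# http://imaging.mrc-cbu.cam.ac.uk/imaging/MniTalairach). Two 3x3 branches,
# selected on the sign of the MNI z coordinate; no translation, so the
# origin is a fixed point. Both branches share their x and y columns, which
# makes the inverse branch selection exact (see brett_tal2mni).

.BRETT_UP <- matrix(c(
  0.9900, 0.0000, 0.0000,
  0.0000, 0.9688, 0.0460,
  0.0000, -0.0485, 0.9189), nrow = 3, byrow = TRUE)

.BRETT_DOWN <- matrix(c(
  0.9900, 0.0000, 0.0000,
  0.0000, 0.9688, 0.0420,
  0.0000, -0.0485, 0.8390), nrow = 3, byrow = TRUE)

.BRETT_UP_INV <- solve(.BRETT_UP)
.BRETT_DOWN_INV <- solve(.BRETT_DOWN)

# Lancaster et al. (2007, Hum Brain Mapp 28:1194-1205) icbm2tal affines,
# mapping ICBM-152/MNI mm coordinates to Talairach mm coordinates.
# "spm" is the icbm_spm2tal variant (for coordinates from SPM-normalised
# images; the default here), "fsl" the icbm_fsl2tal variant. Coefficients
# transcribed from the published icbm_spm2tal.m / icbm_fsl2tal.m.

.LANCASTER <- list(
  spm = matrix(c(
    0.9254, 0.0024, -0.0118, -1.0207,
    -0.0048, 0.9316, -0.0871, -1.7667,
    0.0152, 0.0883, 0.8924, 4.0926,
    0, 0, 0, 1), nrow = 4, byrow = TRUE),
  fsl = matrix(c(
    0.9464, 0.0034, -0.0026, -1.0680,
    -0.0083, 0.9479, -0.0580, -1.0239,
    0.0053, 0.0617, 0.9010, 3.1883,
    0, 0, 0, 1), nrow = 4, byrow = TRUE)
)

# recognised coordinate-space dialects for foci tables
.SPACES <- c("TAL_NATIVE", "MNI", "TAL_BRETT")
.DIRECTIONS <- c("DEFICIT", "EXCESS")
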