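# shared fixtures: everything is generated in code at test time

quick_geometry <- function(...) phantom_geometry(...)

clean_optics <- function(...) phantom_optics(base_noise_sd = 0, ...)

in_focus <- function(art = 100) acquisition_setting("middle", art, 0)

# small study table built by hand, one subject x setting cell
tiny_table <- function(vri, subject = 1L, setting = "middle_art100_f0",
                       repetition = 1L) {
  n <- length(vri)
  data.frame(subject = subject, position = "middle", art = 100L,
             focus = 0, setting = setting, repetition = repetition,
             section = seq_len(n), vri = vri,
             vitreous_mean = vri * 0.85, rpe_mean = 0.85,
             failed = is.na(vri), stringsAsFactors = FALSE)
}

# group RMS oracle for the variability pipeline: direct per-group
# root-mean-square of squared residuals, no GLM involved
rms_by_group <- function(resid_table, group_col) {
  sq <- tapply(resid_table$squared_residual, resid_table[[group_col]], mean)
  sqrt(c(sq))
}
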