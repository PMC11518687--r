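# Shared fixtures: tiny cohorts generated in code, and roster-only manifests
# (no image files) for pure-logic tests.

# A manifest with patients and labels but no images on disk.
roster_manifest <- function(class_counts, images_per_patient = 1L) {
  classes <- names(class_counts)
  recs <- list()
  p <- 0L
  for (cl in classes) {
    for (i in seq_len(class_counts[[cl]])) {
      p <- p + 1L
      pid <- sprintf("pt%04d", p)
      for (j in seq_len(images_per_patient)) {
        recs[[length(recs) + 1L]] <- data.frame(
          image_id = sprintf("%s_img%02d", pid, j), patient_id = pid,
          class = cl, view = "unknown",
          path = file.path("none", sprintf("%s_img%02d.png", pid, j)),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  sonoclean:::manifest_from_records(do.call(rbind, recs), classes)
}

# Generate (and memoize per session) a small imaged cohort in tempdir.
tiny_cohort <- local({
  cache <- list()
  function(tag = "default", n_per_class = 8L, outlier_fraction = 0,
           outlier_modes = c("blank", "blur", "occlude", "label_swap"),
           separation = 0.8, image_size = 48L, seed = 7L) {
    if (!is.null(cache[[tag]])) {
      return(cache[[tag]])
    }
    cfg <- synthetic_config(
      n_patients_per_class = n_per_class,
      image_size = image_size, separation = separation,
      outlier_fraction = outlier_fraction, outlier_modes = outlier_modes,
      seed = seed
    )
    out <- generate_cohort(cfg, file.path(tempdir(), paste0("coh_", tag)))
    cache[[tag]] <<- out
    out
  }
})
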