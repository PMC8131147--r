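#' Standard 32-channel electrode montage
#'
#' Returns the 32-electrode 10-20/10-10 subset used by common 32-channel EEG
#' caps (the layout used by consumer affect corpora), with 2-D scalp
#' coordinates from an azimuthal-equidistant projection onto the unit disc:
#' Cz at the origin, the Fp/T/O circumference ring at radius 1, nose at the
#' top (+y), right ear at +x.
#'
#' @return A data frame with columns `name`, `x`, `y` (unit-disc coordinates)
#'   and `frontal` (logical; `TRUE` for the frontal group Fp1, Fp2, F3, F4,
#'   F7, F8, Fz, AF3, AF4).
#' @examples
#' m <- montage_32()
#' plot(m$x, m$y, asp = 1); text(m$x, m$y, m$name, pos = 3, cex = 0.6)
#' @export
montage_32 <- function() {
  # r: projected radius (1 = circumference ring); phi: degrees clockwise
  # from the nose, so negative angles are over the left hemisphere.
  tab <- list(
    c("Fp1", 1.00,  -18), c("Fp2", 1.00,   18),
    c("AF3", 0.80,  -23), c("AF4", 0.80,   23),
    c("F7",  1.00,  -54), c("F8",  1.00,   54),
    c("F3",  0.65,  -39), c("Fz",  0.50,    0), c("F4",  0.65,  39),
    c("FC5", 0.78,  -69), c("FC1", 0.35,  -52),
    c("FC2", 0.35,   52), c("FC6", 0.78,   69),
    c("T7",  1.00,  -90), c("C3",  0.50,  -90), c("Cz",  0.00,    0),
    c("C4",  0.50,   90), c("T8",  1.00,   90),
    c("CP5", 0.78, -111), c("CP1", 0.35, -128),
    c("CP2", 0.35,  128), c("CP6", 0.78,  111),
    c("P7",  1.00, -126), c("P3",  0.65, -141), c("Pz",  0.50,  180),
    c("P4",  0.65,  141), c("P8",  1.00,  126),
    c("PO3", 0.80, -157), c("PO4", 0.80,  157),
    c("O1",  1.00, -162), c("Oz",  1.00,  180), c("O2",  1.00,  162)
  )
  name <- vapply(tab, `[`, character(1), 1L)
  r <- as.numeric(vapply(tab, `[`, character(1), 2L))
  phi <- as.numeric(vapply(tab, `[`, character(1), 3L)) * pi / 180
  frontal_set <- c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz", "AF3", "AF4")
  data.frame(
    name = name,
    x = r * sin(phi),
    y = r * cos(phi),
    frontal = name %in% frontal_set,
    stringsAsFactors = FALSE
  )
}

#' Write a montage to CSV
#'
#' @param montage A data frame as returned by [montage_32()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(montage, path) {
  utils::write.csv(montage[, c("name", "x", "y")], path, row.names = FALSE)
  invisible(path)
}
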