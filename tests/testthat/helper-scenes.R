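# Scene helpers shared across test files.

# small 4 x 5 layout for fast unit-test renders (ring of controls with POS
# corners, 1 replicate per biomarker + 3 controls inside)
miniLayout <- function() {
  roles <- matrix("NEG", 4L, 5L)
  roles[1L, ] <- c("POS", "NEG", "POS", "NEG", "POS")
  roles[4L, ] <- c("POS", "NEG", "POS", "NEG", "POS")
  roles[2:3, 1L] <- c("POS", "NEG")
  roles[2:3, 5L] <- c("NEG", "POS")
  roles[2L, 2:4] <- c("RBST", "IGF1_100", "IGF1_250")
  roles[3L, 2:4] <- c("POS", "NEG", "POS")
  arrayLayout(roles, pitch = c(30, 30), origin = c(22.5, 22.5),
              ellipse = c(9, 7))
}

identityAberration <- function() {
  list(rotation = 0, shear = 0, scale = c(1, 1), translation = c(0, 0),
       bow = c(0, 0))
}

cleanSpec <- function(layout = miniLayout(), aberration = identityAberration(),
                      noise = list(sd = 0, scale = 0), seed = 1L, ...) {
  sceneSpec(layout = layout,
            background = list(base = 20, gradient = c(0, 0), vignette = 0),
            aberration = aberration, noise = noise, seed = seed, ...)
}
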