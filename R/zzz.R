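.onLoad <- function(libname, pkgname) {
  # built-in landmark-based backend; user backends register alongside it
  if (!"landmark_warp" %in% names(.atkEnv$backends)) {
    registerBackend("landmark_warp", .landmarkWarpBackend)
  }
}
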