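# Shared coarse screening conditions for solver-heavy tests: the
# homogeneous water host (substrate physics is validated separately
# against closed forms), d/8 voxels, 5-point fitting grids, relaxed
# residual. Tests that share these settings also share the session
# cache of bare-sensor states.
coarse_template <- function() scene_template(substrate = FALSE)
coarse_opts <- function() sweep_options(fine_points = 5,
                                        settings = solver_settings(tol = 3e-4))
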