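# Synthetic coastal-demo model (NOT fitted to any real data): linear trend,
# Matern 5/2 correlation with geometric anisotropy. Pairs with
# syntheticBayCandidates() for exercising masked, non-convex regions.
family: matern
phi: 0.25
kappa: 2.5
angle: 0.35
ratio: 1.6
trend: linear
sigma2: 0.8
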