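name,elastic_modulus_MPa,poisson_ratio,constitutive_tag
Cortical bone,12000,0.3,linear elastic
Outer layer of fibrous ring,550,0.3,transversely isotropic linear elastic
Fiber ring second layer,490,0.3,transversely isotropic linear elastic
Fiber ring third layer,440,0.3,transversely isotropic linear elastic
Cancellous bone,100,0.2,hyperelastic (treated as linear elastic)
Cartilaginous endplate,25,0.3,linear elastic
Ligamentum flavum,15,0.3,linear elastic
Posterior longitudinal ligament,10,0.3,linear elastic
Interspinous ligament,10,0.3,linear elastic
Intertransvers ligament,10,0.3,linear elastic
Supraspinal ligament,8,0.3,linear elastic
Anterior longitudinal,8,0.3,linear elastic
Nucleus pulposus,1,0.5,linear elastic
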