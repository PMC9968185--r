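method,pathway
milling,kinetic
ball-milling,kinetic
ball milling,kinetic
cryo-milling,kinetic
cryomilling,kinetic
cryogenic milling,kinetic
vibrational milling,kinetic
spray-drying,kinetic
spray drying,kinetic
freeze-drying,kinetic
freeze drying,kinetic
lyophilization,kinetic
melt-quench,thermodynamic
melt quenching,thermodynamic
quench-cooling,thermodynamic
quench cooling,thermodynamic
co-melting,thermodynamic
melting,thermodynamic
hot-melt extrusion,thermodynamic
hot melt extrusion,thermodynamic
solvent evaporation,thermodynamic
solvent-evaporation,thermodynamic
rotary evaporation,thermodynamic
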