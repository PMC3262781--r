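create neutral/cell
create compartment/cell/soma
setfield/cell/soma dia 2e-05
setfield/cell/soma len 4.47e-05
setfield/cell/soma Cm 4.57537e-11
setfield/cell/soma Em -0.0800
setfield/cell/soma Vm_init -0.068
setfield/cell/soma inject 1e-9
setfield/cell/soma Ra 360502
setfield/cell/soma Rm 3.58441e+08
reset step 0.5 -time
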