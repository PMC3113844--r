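population_id	lat	lon	label
Montevideo, Uruguay	-34.90	-56.19	Montevideo (city)
Buenos Aires, Argentina	-34.61	-58.38	Buenos Aires (city)
Mercedes, Uruguay	-33.25	-58.03	Mercedes, Soriano
Constitución, Uruguay	-31.08	-57.83	Constitucion, Salto
Tupambaé, Uruguay	-32.83	-54.74	Tupambae, Cerro Largo
Rocha, Uruguay	-34.48	-54.34	Rocha (city)
Canelones, Uruguay	-34.52	-56.28	Canelones (city)
Chuy, Uruguay	-33.70	-53.46	Chuy, Rocha
Trinidad, Uruguay	-33.52	-56.90	Trinidad, Flores
Artigas, Uruguay	-30.40	-56.47	Artigas (city)
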