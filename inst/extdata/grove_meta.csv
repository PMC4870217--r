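population_id,lat,long,area,group,n_sampled,families,rst_group,abc_deme
Placer,39.057,-120.574,1,Placer,8,4,Placer,
N_Calaveras,38.279,-120.302,24,Calaveras,29,8,N_Calaveras,Calaveras
S_Calaveras,38.247,-120.240,184,Calaveras,21,8,S_Calaveras,Calaveras
Tuolumne,37.769,-119.807,8,TuolumneMerced,8,7,Tuolumne,TuolumneMerced
Merced,37.750,-119.839,8,TuolumneMerced,8,2,Merced,TuolumneMerced
Mariposa,37.509,-119.604,101,MariposaNelder,15,5,Mariposa,MariposaNelder
Nelder,37.435,-119.590,195,MariposaNelder,29,8,Nelder,MariposaNelder
McKinley,37.023,-119.105,22,McKinley,19,7,McKinley,McKinley
Cabin_Creek,36.806,-118.941,40,South,21,7,South,South
Converse_Basin,36.809,-118.977,1498,South,21,10,South,South
Lockwood,36.793,-118.841,40,South,10,4,South,South
Windy_Gulch,36.766,-118.811,405,South,13,3,South,South
Grant,36.750,-118.984,130,South,2,2,South,South
Redwood_Mtn,36.694,-118.916,1271,South,17,7,South,South
Giant_Forest,36.565,-118.752,855,South,17,5,South,South
Atwell_Mill,36.468,-118.674,383,South,18,7,South,South
Mountain_Home,36.358,-118.706,97,South,8,4,South,South
Black_Mtn_1,36.230,-118.681,1620,South,17,4,South,South
Black_Mtn_2,36.140,-118.513,498,South,30,6,South,South
Wheel_Meadow,36.118,-118.679,669,South,13,9,South,South
Packsaddle,36.102,-118.649,669,South,16,5,South,South
South_Fork,35.929,-118.592,137,South,12,5,South,South
Deer_Creek,35.872,-118.609,21,South,5,4,South,South
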