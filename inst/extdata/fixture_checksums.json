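{
  "brownian_movie.tif": "9c59d05c21fc6d33e8679d8c09aa7b84",
  "brownian_movie.meta.json": "88566a1cc608fcd3501f00ab8aca3d4f",
  "brownian_truth.csv": "0457d8b25c13c5e4c954b6d56be5fec5",
  "brownian_truth.meta.json": "c26a4763fe4d282c8316ff1e190f518a",
  "arrested_movie.tif": "7ac0d8222d866458925fb91f05902f70",
  "arrested_movie.meta.json": "88566a1cc608fcd3501f00ab8aca3d4f",
  "arrested_truth.csv": "a00e74cf4b49e1529e44e5b40b3d8e55",
  "arrested_truth.meta.json": "c26a4763fe4d282c8316ff1e190f518a",
  "PAO1_like/scenario.json": "24d505123f8a2f7dacea793bdb66df9f",
  "PAO1_like/trajectories_age00000060.csv": "236647c215f1fc3fcbc28243891cc896",
  "PAO1_like/trajectories_age00000060.meta.json": "d68a8cd851f7e852b5e628fb2b4519a8",
  "PAO1_like/trajectories_age00000300.csv": "8b9917da953f5b3e3a67ebb7f99315bd",
  "PAO1_like/trajectories_age00000300.meta.json": "3dc102a216ee726e68d38f0547fbbc66",
  "PAO1_like/trajectories_age00000900.csv": "02c64a57efc7f8a9ce455afdeb80598a",
  "PAO1_like/trajectories_age00000900.meta.json": "b97051bcadb0b1c6d7b22430d18252b4",
  "PAO1_like/trajectories_age00001800.csv": "2437037d2e05f39f1b634ea668fdddc7",
  "PAO1_like/trajectories_age00001800.meta.json": "d02c166f5a20b919698c411b6e66abc2",
  "PAO1_like/trajectories_age00003600.csv": "86be5d5c4165de00966a512f49ce5ebc",
  "PAO1_like/trajectories_age00003600.meta.json": "17f9082606edfac5ff906801c0ecebf3",
  "PAO1_like/trajectories_age00005400.csv": "e203bcc36312cb4476641c7e078ebc01",
  "PAO1_like/trajectories_age00005400.meta.json": "db1ed6bf8f80efb6fe18041f84ca6c96",
  "PAO1_like/trajectories_age00007200.csv": "4c469978eddb341d49de9606b5fce6d3",
  "PAO1_like/trajectories_age00007200.meta.json": "e45b3da98388f4e6bea2ed8f1d2943bb",
  "PAO1_like/trajectories_age00010000.csv": "b1e2e531a1089c4a029df5df4ff1b92e",
  "PAO1_like/trajectories_age00010000.meta.json": "a2b33a4584381915c3695c204610ace8",
  "PAO1_like/trajectories_age00020000.csv": "f4acb01002913ea0ef20422dc4ec53d7",
  "PAO1_like/trajectories_age00020000.meta.json": "686920e693441078c629cd860ebf1b24",
  "PAO1_like/trajectories_age00040000.csv": "6f9b5cc6cba06bb7cbe14e1de2112bc8",
  "PAO1_like/trajectories_age00040000.meta.json": "dc9f164ee1d1c495ac8797c0a6c33725",
  "PAO1_like/trajectories_age00080000.csv": "96e18a314160ddb620519079234ba943",
  "PAO1_like/trajectories_age00080000.meta.json": "13da04c5d0e6ba604faa0ab35106cdbe",
  "PAO1_like/ages.json": "f3054e6e4799a6f824779b29b5b69f7a",
  "PA14_like/scenario.json": "d104a93a8f1e4c01247fa602398712ce",
  "PA14_like/trajectories_age00000060.csv": "236647c215f1fc3fcbc28243891cc896",
  "PA14_like/trajectories_age00000060.meta.json": "d68a8cd851f7e852b5e628fb2b4519a8",
  "PA14_like/trajectories_age00000300.csv": "8b9917da953f5b3e3a67ebb7f99315bd",
  "PA14_like/trajectories_age00000300.meta.json": "3dc102a216ee726e68d38f0547fbbc66",
  "PA14_like/trajectories_age00000900.csv": "02c64a57efc7f8a9ce455afdeb80598a",
  "PA14_like/trajectories_age00000900.meta.json": "b97051bcadb0b1c6d7b22430d18252b4",
  "PA14_like/trajectories_age00001800.csv": "2437037d2e05f39f1b634ea668fdddc7",
  "PA14_like/trajectories_age00001800.meta.json": "d02c166f5a20b919698c411b6e66abc2",
  "PA14_like/trajectories_age00003600.csv": "cd513c8750ccb7aa075d5aaba93ae602",
  "PA14_like/trajectories_age00003600.meta.json": "17f9082606edfac5ff906801c0ecebf3",
  "PA14_like/trajectories_age00005400.csv": "ef700a25216e9bdf1e59b5532cfbd041",
  "PA14_like/trajectories_age00005400.meta.json": "db1ed6bf8f80efb6fe18041f84ca6c96",
  "PA14_like/trajectories_age00007200.csv": "b6e597e4f75fa34599059edbee8f36e4",
  "PA14_like/trajectories_age00007200.meta.json": "e45b3da98388f4e6bea2ed8f1d2943bb",
  "PA14_like/trajectories_age00010000.csv": "c27d636b91db6d85d9f22e14b5efa4b7",
  "PA14_like/trajectories_age00010000.meta.json": "a2b33a4584381915c3695c204610ace8",
  "PA14_like/trajectories_age00020000.csv": "2a7579441dfec91303a5d8e9e5227e00",
  "PA14_like/trajectories_age00020000.meta.json": "686920e693441078c629cd860ebf1b24",
  "PA14_like/trajectories_age00040000.csv": "bc11e578b6ae849d6f94de19caa28012",
  "PA14_like/trajectories_age00040000.meta.json": "dc9f164ee1d1c495ac8797c0a6c33725",
  "PA14_like/trajectories_age00080000.csv": "7409c2c07808f34f610687b3a957e688",
  "PA14_like/trajectories_age00080000.meta.json": "13da04c5d0e6ba604faa0ab35106cdbe",
  "PA14_like/ages.json": "f3054e6e4799a6f824779b29b5b69f7a",
  "expected.json": "56d68cb52be9b9938367a3dc357c5b87"
}
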